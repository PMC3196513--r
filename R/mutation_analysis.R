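#' Construct an annotation track
#'
#' A minimal gene-interval annotation: name, 1-based closed interval, strand,
#' whether the feature is protein-coding, the reading-frame offset of the
#' first codon base relative to `start` (plus strand) or `end` (minus
#' strand), and a flag for genes annotated only as conserved or predicted
#' proteins (unknown-function genes), which are tallied in their own class.
#'
#' @param name Gene names.
#' @param start,end 1-based closed interval bounds, `start <= end`.
#' @param strand "+" or "-".
#' @param coding Logical: translate SNPs inside this feature?
#' @param frame Frame offset in {0, 1, 2} (default 0).
#' @param unknown_function Logical: conserved/predicted-protein gene?
#' @return A data.frame of class `annotation_track`.
#' @export
annotation_track <- function(name, start, end, strand = "+", coding = TRUE,
                             frame = 0L, unknown_function = FALSE) {
  n <- length(name)
  df <- data.frame(name = name, start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(strand, n),
                   coding = rep_len(coding, n),
                   frame = rep_len(as.integer(frame), n),
                   unknown_function = rep_len(unknown_function, n))
  stopifnot(all(df$start <= df$end), all(df$start >= 1),
            all(df$strand %in% c("+", "-")), all(df$frame %in% 0:2))
  structure(df, class = c("annotation_track", "data.frame"))
}

# Codon translation via the standard genetic code, which coincides with the
# bacterial/archaeal code (table 11) for every internal codon; start-codon
# special cases are irrelevant to substitution classification.
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

#' Classify a SNP against a gene annotation
#'
#' Intergenic if the position lies outside every annotated interval; inside a
#' gene flagged as unknown-function, class `unknown-function-gene`; inside a
#' coding gene, the containing codon is translated strand-aware with the
#' reference and alternate base, yielding `synonymous` or `nonsynonymous`;
#' inside a non-coding feature, `intergenic` does not apply and the class is
#' `unknown`. Indel calls are classed `unknown`.
#'
#' @param position 1-based genomic position of the SNP.
#' @param ref_base,alt_base Reference and alternate bases (plus-strand
#'   orientation, as in a VCF).
#' @param annotation An [annotation_track()].
#' @param genome Genome sequence (character string).
#' @return One of "synonymous", "nonsynonymous", "intergenic",
#'   "unknown-function-gene", "unknown".
#' @export
classify_mutation <- function(position, ref_base, alt_base, annotation,
                              genome) {
  L <- nchar(genome)
  if (position < 1 || position > L) {
    stop("position ", position, " outside genome bounds [1, ", L, "]")
  }
  if (!ref_base %in% BASES || !alt_base %in% BASES) return("unknown")
  hit <- which(annotation$start <= position & annotation$end >= position)
  if (length(hit) == 0) return("intergenic")
  g <- annotation[hit[1], ]
  if (isTRUE(g$unknown_function)) return("unknown-function-gene")
  if (!isTRUE(g$coding)) return("unknown")

  if (g$strand == "+") {
    offset <- position - g$start - g$frame
    if (offset < 0) return("unknown")
    codon_start <- g$start + g$frame + 3L * (offset %/% 3L)
    if (codon_start + 2L > L) return("unknown")
    codon <- substring(genome, codon_start, codon_start + 2L)
    idx <- position - codon_start + 1L
    ref_codon <- codon
    alt_codon <- codon
    substr(ref_codon, idx, idx) <- ref_base
    substr(alt_codon, idx, idx) <- alt_base
  } else {
    offset <- g$end - position - g$frame
    if (offset < 0) return("unknown")
    codon_end <- g$end - g$frame - 3L * (offset %/% 3L)
    if (codon_end - 2L < 1L) return("unknown")
    # codon read 3' -> 5' on the plus strand, then complemented
    plus <- substring(genome, codon_end - 2L, codon_end)
    codon <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(plus)))
    idx <- codon_end - position + 1L  # 1..3 within the rc codon
    ref_codon <- codon
    alt_codon <- codon
    substr(ref_codon, idx, idx) <- comp_base(ref_base)
    substr(alt_codon, idx, idx) <- comp_base(alt_base)
  }
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  if (is.na(aa_ref) || is.na(aa_alt)) return("unknown")
  if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
}

#' Classify a table of SNP calls
#'
#' @param calls `snp_calls` data.frame (columns `position`, `ref_base`,
#'   `called_base`).
#' @param annotation An [annotation_track()].
#' @param genome Genome sequence.
#' @return The calls with an added `class` column, plus a `class_counts`
#'   attribute (named integer vector).
#' @export
classify_calls <- function(calls, annotation, genome) {
  cls <- vapply(seq_len(nrow(calls)), function(i) {
    classify_mutation(calls$position[i], calls$ref_base[i],
                      calls$called_base[i], annotation, genome)
  }, character(1))
  calls$class <- cls
  attr(calls, "class_counts") <- table(factor(
    cls, levels = c("nonsynonymous", "synonymous", "intergenic",
                    "unknown-function-gene", "unknown")))
  calls
}

#' Partition mutations by the subset of strains sharing them
#'
#' Given per-strain mutation sets keyed by `position:alt` (nucleotide-level
#' identity), returns the exact membership partition of their union: one cell
#' per non-empty strain subset, as in a Venn-diagram comparison of evolved
#' strains.
#'
#' @param strain_sets Named list; each element a character vector of mutation
#'   keys (or a `snp_calls` data.frame, keyed automatically).
#' @return A list of class `overlap_partition`: `cells` (named list, names
#'   like "A+B", values the mutation keys unique to that strain subset),
#'   `sizes`, and `union_size`.
#' @export
overlap_partition <- function(strain_sets) {
  stopifnot(length(strain_sets) >= 2, !is.null(names(strain_sets)))
  keys <- lapply(strain_sets, function(s) {
    if (is.data.frame(s)) unique(paste0(s$position, ":", s$called_base))
    else unique(as.character(s))
  })
  universe <- unique(unlist(keys, use.names = FALSE))
  membership <- vapply(keys, function(k) universe %in% k,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, names(keys)))
  label <- apply(membership, 1, function(m) {
    paste(names(keys)[m], collapse = "+")
  })
  cells <- split(universe, label)
  structure(list(cells = cells,
                 sizes = vapply(cells, length, integer(1)),
                 union_size = length(universe)),
            class = "overlap_partition")
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat(sprintf("<overlap_partition> union of %d mutations\n", x$union_size))
  for (nm in names(x$sizes)) cat(sprintf("  %-20s %d\n", nm, x$sizes[[nm]]))
  invisible(x)
}

#' Observed mutations per cell division
#'
#' Normalizes an endpoint's mutation count by the cumulative cell divisions
#' of its evolution. This is an observed per-lineage count per population
#' division — a descriptive supply statistic on the CCD timescale — not a
#' Luria-Delbruck fluctuation-test mutation-rate estimator.
#'
#' @param mutation_count Number of mutations in the endpoint clone (>= 0).
#' @param ccd Cumulative cell divisions of the evolution (> 0).
#' @return Mutations per cell division.
#' @export
mutations_per_division <- function(mutation_count, ccd) {
  stopifnot(mutation_count >= 0)
  if (any(ccd <= 0)) stop("ccd must be strictly positive")
  mutation_count / ccd
}
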