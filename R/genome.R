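BASES <- c("A", "C", "G", "T")

#' Generate a random reference genome
#'
#' @param length Genome length in bases (>= 1).
#' @param gc Target GC fraction (default 0.5).
#' @return A single character string over {A,C,G,T}.
#' @export
generate_genome <- function(length, gc = 0.5) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate short single-end reads from a genome
#'
#' Reads are placed uniformly on both strands. Each base suffers an
#' independent substitution error at `error_rate` and is independently
#' replaced by the ambiguity mark `'.'` at `ambiguous_rate` (the instrument
#' dialect this pipeline curates on).
#'
#' @param genome Reference sequence (character string over {A,C,G,T}).
#' @param coverage Mean per-base coverage (> 0); the read count is
#'   `round(coverage * length / read_length)`.
#' @param read_length Read length in bases (default 36).
#' @param error_rate Per-base substitution error probability (default 0).
#' @param ambiguous_rate Per-base probability of an ambiguous '.' call
#'   (default 0).
#' @return A data.frame of class `read_set` with columns `id`, `bases`,
#'   `true_start` (1-based placement on the genome) and `true_strand`.
#' @export
simulate_reads <- function(genome, coverage, read_length = 36,
                           error_rate = 0, ambiguous_rate = 0) {
  L <- nchar(genome)
  stopifnot(L >= read_length)
  if (coverage <= 0) stop("coverage must be positive")
  n_reads <- round(coverage * L / read_length)
  starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  seqs <- substring(genome, starts, starts + read_length - 1L)
  minus <- strands == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])

  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = read_length)
  if (error_rate > 0) {
    err <- which(runif(length(mat)) < error_rate)
    if (length(err)) {
      # substitute with a uniformly chosen different base
      cur <- mat[err]
      mat[err] <- vapply(cur, function(b) sample(setdiff(BASES, b), 1),
                         character(1), USE.NAMES = FALSE)
    }
  }
  if (ambiguous_rate > 0) {
    amb <- runif(length(mat)) < ambiguous_rate
    mat[amb] <- "."
  }
  seqs <- apply(mat, 2, paste, collapse = "")
  structure(data.frame(
    id = sprintf("read_%06d", seq_len(n_reads)),
    bases = seqs,
    true_start = starts,
    true_strand = strands
  ), class = c("read_set", "data.frame"))
}

#' Spike known non-overlapping mutations into a reference
#'
#' Plants `n` mutations (SNPs, single-base insertions and deletions in the
#' proportions of `type_mix`) at uniformly random, pairwise non-overlapping
#' sites, and returns both the mutated reference and the coordinate-mapped
#' truth set used for false-negative estimation. Footprints (intervals on the
#' mutated reference) are pairwise disjoint; a deletion's footprint is the
#' single junction base following the deleted site.
#'
#' @param ref Reference sequence (character string over {A,C,G,T}).
#' @param n Number of mutations (default 1000).
#' @param type_mix Named proportions for types `SNP`, `insertion`, `deletion`
#'   (default equal thirds; counts by largest remainder).
#' @param indel_length Length of inserted/deleted tracts (default 1).
#' @return A list with `mutated_ref` (character string) and `truth`, a
#'   data.frame with columns `type`, `position` (1-based on the original
#'   reference), `ref`, `alt`, `fp_start`, `fp_end` (1-based closed footprint
#'   on the mutated reference).
#' @export
spike_mutations <- function(ref, n = 1000,
                            type_mix = c(SNP = 1, insertion = 1, deletion = 1) / 3,
                            indel_length = 1) {
  L <- nchar(ref)
  stopifnot(n >= 1, indel_length >= 1)
  if (L < n * (indel_length + 2) * 3) {
    stop("reference too short to place ", n, " disjoint mutations")
  }
  type_mix <- type_mix / sum(type_mix)
  counts <- apportion(type_mix[c("SNP", "insertion", "deletion")], n)
  types <- rep(c("SNP", "insertion", "deletion"), times = counts)

  # sample uniform anchor sites, enforcing a minimum gap so that footprints
  # (incl. deletion junctions) cannot touch
  gap <- indel_length + 2L
  anchors <- integer(0)
  for (attempt in 1:50) {
    cand <- sort(unique(c(anchors,
                          sample.int(L - indel_length, 2L * n))))
    keep <- rep(TRUE, length(cand))
    last <- -gap
    for (i in seq_along(cand)) {
      if (cand[i] - last < gap) keep[i] <- FALSE else last <- cand[i]
    }
    anchors <- cand[keep]
    if (length(anchors) >= n) break
  }
  if (length(anchors) < n) stop("cannot place ", n, " disjoint mutations")
  anchors <- sort(sample(anchors, n))
  types <- sample(types)   # shuffle types across ordered anchors

  refbase <- substring(ref, anchors, anchors)
  alt <- character(n)
  for (i in seq_len(n)) {
    alt[i] <- switch(types[i],
      SNP = sample(setdiff(BASES, refbase[i]), 1),
      insertion = paste(sample(BASES, indel_length, replace = TRUE),
                        collapse = ""),
      deletion = "")
  }

  # build the mutated reference left to right, tracking the coordinate shift
  pieces <- character(0)
  fp_start <- fp_end <- integer(n)
  prev <- 1L
  shift <- 0L
  for (i in seq_len(n)) {
    p <- anchors[i]
    pm <- p + shift            # anchor position on the mutated reference
    if (types[i] == "SNP") {
      pieces <- c(pieces, substring(ref, prev, p - 1L), alt[i])
      fp_start[i] <- pm; fp_end[i] <- pm
      prev <- p + 1L
    } else if (types[i] == "insertion") {
      # insert after the anchor base
      pieces <- c(pieces, substring(ref, prev, p), alt[i])
      fp_start[i] <- pm + 1L; fp_end[i] <- pm + indel_length
      prev <- p + 1L
      shift <- shift + indel_length
    } else {                   # deletion of indel_length bases at the anchor
      pieces <- c(pieces, substring(ref, prev, p - 1L))
      fp_start[i] <- pm; fp_end[i] <- pm  # junction base after the deletion
      prev <- p + indel_length
      shift <- shift - indel_length
    }
  }
  pieces <- c(pieces, substring(ref, prev, L))
  mutated <- paste(pieces, collapse = "")

  truth <- data.frame(type = types, position = anchors,
                      ref = ifelse(types == "insertion", refbase,
                                   ifelse(types == "deletion",
                                          substring(ref, anchors,
                                                    anchors + indel_length - 1L),
                                          refbase)),
                      alt = alt, fp_start = fp_start, fp_end = fp_end)
  list(mutated_ref = mutated, truth = truth)
}

#' Apply a truth mutation set to a reference
#'
#' Reconstructs the mutated reference from the original and a truth table, as
#' a constructive identity check on [spike_mutations()].
#'
#' @param ref Original reference sequence.
#' @param truth Truth table from [spike_mutations()].
#' @return The mutated reference sequence.
#' @export
apply_mutations <- function(ref, truth) {
  truth <- truth[order(truth$position), , drop = FALSE]
  pieces <- character(0)
  prev <- 1L
  for (i in seq_len(nrow(truth))) {
    p <- truth$position[i]
    if (truth$type[i] == "SNP") {
      pieces <- c(pieces, substring(ref, prev, p - 1L), truth$alt[i])
      prev <- p + 1L
    } else if (truth$type[i] == "insertion") {
      pieces <- c(pieces, substring(ref, prev, p), truth$alt[i])
      prev <- p + 1L
    } else {
      pieces <- c(pieces, substring(ref, prev, p - 1L))
      prev <- p + nchar(truth$ref[i])
    }
  }
  paste(c(pieces, substring(ref, prev, nchar(ref))), collapse = "")
}
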