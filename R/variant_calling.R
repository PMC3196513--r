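#' Curate raw reads
#'
#' Removes every read containing an ambiguous base: the period mark emitted
#' by the sequencer dialect this pipeline targets, and its modern equivalent
#' 'N'.
#'
#' @param reads A `read_set` data.frame (from [simulate_reads()] or
#'   [read_fastq()]) or a character vector of read sequences.
#' @return The retained reads, same type as the input.
#' @export
curate_reads <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$bases else reads
  keep <- !grepl("[.N]", seqs)
  if (is.data.frame(reads)) {
    out <- reads[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    reads[keep]
  }
}

#' Iteratively align reads with an increasing mismatch cap
#'
#' Ungapped both-strand placement of each read against the reference. The
#' mismatch limit is raised one unit at a time (default 0 to 5); reads left
#' unaligned at one limit are re-attempted at the next. A read is placed only
#' at a unique best-scoring position (ties across positions or strands leave
#' it unaligned at every limit, since the tie persists). The iteration at
#' which a read is placed therefore equals the smallest limit admitting its
#' best-scoring placement.
#'
#' @param reads A `read_set` data.frame or character vector of sequences
#'   (curate first: see [curate_reads()]).
#' @param ref Reference sequence (character string).
#' @param limits Integer vector of mismatch limits tried in order
#'   (default 0:5).
#' @return A list with `alignments` (data.frame: `id`, `start` 1-based,
#'   `strand`, `mismatch_count`, `iteration`, plus the read `bases`) and
#'   `unaligned` (character vector of read ids never placed).
#' @export
align_iteratively <- function(reads, ref, limits = 0:5) {
  seqs <- if (is.data.frame(reads)) reads$bases else reads
  ids <- if (is.data.frame(reads) && !is.null(reads$id)) reads$id
         else sprintf("read_%06d", seq_along(seqs))
  stopifnot(length(limits) >= 1, all(diff(limits) > 0))
  max_mm <- max(limits)

  scan <- align_scan_cpp(as.character(seqs), ref, as.integer(max_mm))
  if (any(scan$skipped)) {
    warning(sum(scan$skipped), " read(s) longer than the reference; skipped")
  }
  placed <- !is.na(scan$pos) & scan$ties == 1L & !scan$skipped &
    scan$mismatch_count <= max_mm
  iteration <- rep(NA_integer_, length(seqs))
  iteration[placed] <- vapply(scan$mismatch_count[placed], function(mm) {
    as.integer(limits[limits >= mm][1])
  }, integer(1))

  alignments <- data.frame(
    id = ids[placed],
    bases = seqs[placed],
    start = scan$pos[placed],
    strand = scan$strand[placed],
    mismatch_count = scan$mismatch_count[placed],
    iteration = iteration[placed]
  )
  rownames(alignments) <- NULL
  list(alignments = alignments, unaligned = ids[!placed & !scan$skipped])
}

#' Compile alignments into a nucleotide-resolution profile
#'
#' Tallies, at every reference position, the A/C/G/T counts observed in the
#' aligned reads (minus-strand reads are reverse-complemented back into
#' reference orientation). This is the pileup substrate of the SNP rule.
#'
#' @param alignments Alignment data.frame from [align_iteratively()] (needs
#'   columns `bases`, `start`, `strand`).
#' @param ref Reference sequence.
#' @return A 4 x L integer matrix of class `alignment_profile` with rownames
#'   A, C, G, T; attribute `ref` holds the reference.
#' @export
compile_profile <- function(alignments, ref) {
  L <- nchar(ref)
  counts <- matrix(0L, nrow = 4, ncol = L, dimnames = list(BASES, NULL))
  if (nrow(alignments) > 0) {
    seqs <- alignments$bases
    minus <- alignments$strand == "-"
    if (any(minus)) {
      seqs[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[minus])))
    }
    lens <- nchar(seqs)
    chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
    pos <- unlist(lapply(seq_along(seqs), function(i) {
      alignments$start[i] + seq_len(lens[i]) - 1L
    }), use.names = FALSE)
    b <- match(chars, BASES)
    ok <- !is.na(b) & pos >= 1L & pos <= L
    idx <- (pos[ok] - 1L) * 4L + b[ok]
    tab <- tabulate(idx, nbins = 4L * L)
    counts[] <- counts + matrix(tab, nrow = 4)
  }
  structure(counts, ref = ref, class = c("alignment_profile", class(counts)))
}

#' Call SNPs from an alignment profile
#'
#' At every position let `v` be the largest count among non-reference bases
#' and `r` the count of the reference base; a position is called polymorphic
#' iff `v > factor * r` (strict) and `v >= min_variant_count`. The called
#' base is the arg-max non-reference base; a tie between two non-reference
#' bases at the maximum yields no call and the position is flagged ambiguous.
#'
#' @param profile An `alignment_profile` from [compile_profile()].
#' @param ref Reference sequence (defaults to the profile's `ref` attribute).
#' @param factor Threshold multiplier on the reference count (default 2: the
#'   variant count must be greater than twice the reference count).
#' @param min_variant_count Coverage floor on the variant count (default 1,
#'   i.e. the literal threshold rule with no extra floor).
#' @return A data.frame of class `snp_calls`: `position` (1-based),
#'   `ref_base`, `called_base`, `variant_count`, `reference_count`.
#'   Attribute `ambiguous` lists tie-flagged positions.
#' @export
call_snps <- function(profile, ref = attr(profile, "ref"), factor = 2,
                      min_variant_count = 1) {
  L <- ncol(profile)
  stopifnot(nchar(ref) == L)
  ref_idx <- match(strsplit(ref, "", fixed = TRUE)[[1]], BASES)
  counts <- unclass(profile)

  r <- counts[cbind(ref_idx, seq_len(L))]
  nonref <- counts
  nonref[cbind(ref_idx, seq_len(L))] <- -1L
  v <- apply(nonref, 2, max)
  vb <- apply(nonref, 2, which.max)
  n_at_max <- colSums(nonref == rep(v, each = 4)) # ties among non-ref bases

  hit <- v > factor * r & v >= min_variant_count
  ambiguous <- which(hit & n_at_max > 1)
  call <- hit & n_at_max == 1

  out <- data.frame(
    position = which(call),
    ref_base = BASES[ref_idx[call]],
    called_base = BASES[vb[call]],
    variant_count = v[call],
    reference_count = r[call]
  )
  rownames(out) <- NULL
  structure(out, ambiguous = ambiguous,
            class = c("snp_calls", "data.frame"))
}

#' Uniquely mappable positions of a genome
#'
#' A position is uniquely mappable if every read-length window covering it
#' occurs exactly once in the genome across both strands. Determined by an
#' exhaustive window census (the same brute-force semantics as the aligner),
#' and used to restrict spike-in detection analyses to sites where unique
#' placement is possible at all.
#'
#' @param genome Reference sequence.
#' @param read_length Window length (default 36).
#' @return Logical vector of length `nchar(genome)`.
#' @export
mappable_positions <- function(genome, read_length = 36) {
  L <- nchar(genome)
  nw <- L - read_length + 1L
  if (nw < 1) return(rep(FALSE, L))
  starts <- seq_len(nw)
  fwd <- substring(genome, starts, starts + read_length - 1L)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(fwd)))
  tab <- table(c(fwd, rev))
  unique_win <- as.vector(tab[fwd]) == 1L
  # position i is covered by windows starting in [i - read_length + 1, i]
  bad_start <- which(!unique_win)
  bad_pos <- rep(FALSE, L)
  for (s in bad_start) {
    bad_pos[s:(s + read_length - 1L)] <- TRUE
  }
  covered <- rep(FALSE, L)
  covered[1:(nw + read_length - 1L)] <- TRUE
  covered & !bad_pos
}

#' Spike-in detection and false-negative estimation
#'
#' A truth mutation is detected iff some call position falls inside its
#' footprint on the mutated reference, expanded by `match_window` bases on
#' each side. Returns per-type detected fractions and the overall
#' false-negative rate (1 - detected fraction).
#'
#' @param truth Truth table from [spike_mutations()].
#' @param calls `snp_calls` on the mutated-reference coordinate system.
#' @param match_window Footprint expansion in bases (default 0; useful > 0
#'   for indels, which a SNP-resolution caller flags via flanking mismatch
#'   pile-ups).
#' @return A list of class `detection_report`: `per_type` (data.frame with
#'   `type`, `n`, `detected`, `fraction`, `fn_rate`) and `overall`
#'   (detected fraction and FN rate over all spiked mutations).
#' @export
estimate_detection <- function(truth, calls, match_window = 0) {
  pos <- calls$position
  detected <- vapply(seq_len(nrow(truth)), function(i) {
    any(pos >= truth$fp_start[i] - match_window &
        pos <= truth$fp_end[i] + match_window)
  }, logical(1))
  per_type <- do.call(rbind, lapply(split(detected, truth$type), function(d) {
    data.frame(n = length(d), detected = sum(d), fraction = mean(d),
               fn_rate = 1 - mean(d))
  }))
  per_type <- cbind(type = rownames(per_type), per_type)
  rownames(per_type) <- NULL
  structure(list(
    per_type = per_type,
    overall = data.frame(n = nrow(truth), detected = sum(detected),
                         fraction = mean(detected),
                         fn_rate = 1 - mean(detected))
  ), class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat("<detection_report>\n")
  print(x$per_type, row.names = FALSE)
  cat(sprintf("overall detection %.3f (FN %.3f) of %d spiked mutations\n",
              x$overall$fraction, x$overall$fn_rate, x$overall$n))
  invisible(x)
}

#' Run the spike-in false-negative pipeline end to end
#'
#' Plants known mutations in a copy of the reference, simulates reads from
#' the *unmutated* genome (the "endpoint sample"), curates and aligns them
#' against the mutated reference, calls SNPs, and scores detection of each
#' spiked mutation type.
#'
#' @param ref Reference sequence.
#' @param n_spike Number of spiked mutations (default 1000).
#' @param coverage Read coverage (default 30).
#' @param read_length Read length (default 36).
#' @param error_rate,ambiguous_rate Read error model
#'   (see [simulate_reads()]).
#' @param factor,min_variant_count SNP rule parameters (see [call_snps()]).
#' @param match_window Footprint expansion for matching calls to truth.
#' @param seed Optional integer seed for the read/spike randomness.
#' @return A list with `report` (a `detection_report`), `truth`, `calls`,
#'   and `mutated_ref`.
#' @export
fn_rate_analysis <- function(ref, n_spike = 1000, coverage = 30,
                             read_length = 36, error_rate = 0,
                             ambiguous_rate = 0, factor = 2,
                             min_variant_count = 1, match_window = 0,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- spike_mutations(ref, n = n_spike)
  reads <- simulate_reads(ref, coverage = coverage,
                          read_length = read_length,
                          error_rate = error_rate,
                          ambiguous_rate = ambiguous_rate)
  reads <- curate_reads(reads)
  aln <- align_iteratively(reads, sp$mutated_ref)
  prof <- compile_profile(aln$alignments, sp$mutated_ref)
  calls <- call_snps(prof, sp$mutated_ref, factor = factor,
                     min_variant_count = min_variant_count)
  list(report = estimate_detection(sp$truth, calls, match_window),
       truth = sp$truth, calls = calls, mutated_ref = sp$mutated_ref)
}
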