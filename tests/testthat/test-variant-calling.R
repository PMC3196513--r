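test_that("curation removes reads with ambiguous base marks", {
  expect_identical(curate_reads(c("ACGT", "AC.T")), "ACGT")
  expect_identical(curate_reads(c("ACGT", "ACNT")), "ACGT")
  expect_identical(curate_reads(character(0)), character(0))

  set.seed(31)
  g <- generate_genome(3000)
  reads <- simulate_reads(g, coverage = 1000 * 36 / 3000,
                          ambiguous_rate = 0.01)
  kept <- nrow(curate_reads(reads)) / nrow(reads)
  expect_equal(kept, 0.99^36, tolerance = 0.05)
})

test_that("alignment places reads at unique best Hamming positions", {
  set.seed(32)
  g <- generate_genome(1500)
  exact <- substring(g, 100, 135)
  a <- align_iteratively(exact, g)$alignments
  expect_equal(a$start, 100)
  expect_equal(a$mismatch_count, 0)
  expect_equal(a$iteration, 0)
  expect_equal(a$strand, "+")

  # reverse-complement read aligns minus at the substring's coordinates
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(exact)))
  arc <- align_iteratively(rc, g)$alignments
  expect_equal(arc$start, 100)
  expect_equal(arc$strand, "-")

  # six mismatches at the best locus: unalignable at limit 5
  six <- exact
  for (p in c(2, 8, 14, 20, 26, 32)) {
    cur <- substring(six, p, p)
    substr(six, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  out <- align_iteratively(six, g)
  expect_identical(nrow(out$alignments), 0L)
  expect_length(out$unaligned, 1)

  expect_warning(align_iteratively(strrep("A", 40), generate_genome(30)),
                 "longer")
})

test_that("aligner agrees with the brute-force Biostrings oracle", {
  set.seed(33)
  for (instance in 1:25) {
    g <- generate_genome(sample(300:2000, 1))
    reads <- simulate_reads(g, coverage = 15 * 36 / nchar(g),
                            error_rate = sample(c(0, 0.02, 0.1), 1))
    res <- align_iteratively(reads, g)
    byid <- split(res$alignments, res$alignments$id)
    for (i in seq_len(nrow(reads))) {
      o <- oracle_align(reads$bases[i], g)
      mine <- byid[[reads$id[i]]]
      if (isTRUE(o$aligned)) {
        expect_false(is.null(mine))
        expect_equal(mine$start, o$pos)
        expect_equal(mine$strand, o$strand)
        expect_equal(mine$mismatch_count, o$mismatch)
      } else {
        expect_true(is.null(mine))
      }
    }
  }
})

test_that("reads aligned at limit k stay aligned at limit k+1", {
  set.seed(34)
  g <- generate_genome(2000)
  reads <- simulate_reads(g, coverage = 3, error_rate = 0.06)
  prev <- character(0)
  for (k in 0:5) {
    ids <- align_iteratively(reads, g, limits = 0:k)$alignments$id
    expect_true(all(prev %in% ids))
    prev <- ids
  }
})

test_that("profiles count observed nucleotides in reference orientation", {
  g <- "ACGTACGTAC"
  one <- data.frame(id = "r1", bases = "ACGT", start = 1, strand = "+",
                    mismatch_count = 0, iteration = 0)
  p <- compile_profile(one, g)
  expect_equal(unname(p["A", 1]), 1L)
  expect_equal(unname(p["C", 2]), 1L)
  expect_equal(unname(p["G", 3]), 1L)
  expect_equal(unname(p["T", 4]), 1L)
  expect_equal(sum(p), 4L)

  two <- rbind(one, data.frame(id = "r2", bases = "AGGT", start = 1,
                               strand = "+", mismatch_count = 1,
                               iteration = 1))
  p2 <- compile_profile(two, g)
  expect_equal(sum(p2[, 2]), 2L)
  expect_equal(unname(p2["C", 2]), 1L)
  expect_equal(unname(p2["G", 2]), 1L)

  # minus-strand bases are complemented back: read 'ACGT' aligned minus at 1
  # observes reverseComplement('ACGT') = 'ACGT'
  minus <- data.frame(id = "r3", bases = "AAAA", start = 3, strand = "-",
                      mismatch_count = 2, iteration = 2)
  p3 <- compile_profile(minus, g)
  expect_equal(unname(colSums(p3)[3:6]), rep(1L, 4))
  expect_equal(unname(p3["T", 3]), 1L)  # revcomp(AAAA) = TTTT

  # 30x error-free coverage: per-position totals equal a truth-placement
  # pileup oracle exactly
  set.seed(35)
  g2 <- generate_genome(3000)
  reads <- simulate_reads(g2, coverage = 30)
  res <- align_iteratively(reads, g2)
  prof <- compile_profile(res$alignments, g2)
  aligned_truth <- reads[reads$id %in% res$alignments$id, ]
  oracle_cov <- integer(nchar(g2))
  for (i in seq_len(nrow(aligned_truth))) {
    span <- aligned_truth$true_start[i]:(aligned_truth$true_start[i] + 35)
    oracle_cov[span] <- oracle_cov[span] + 1L
  }
  expect_equal(unname(colSums(prof)), oracle_cov)
})

test_that("the threshold rule calls strictly above factor x reference", {
  mk_profile <- function(ref, counts) {
    p <- matrix(0L, 4, nchar(ref), dimnames = list(c("A", "C", "G", "T"), NULL))
    for (b in names(counts)) p[b, 1] <- counts[[b]]
    structure(p, ref = ref, class = c("alignment_profile", class(p)))
  }
  g7 <- call_snps(mk_profile("A", list(A = 3L, G = 7L)))
  expect_equal(g7$called_base, "G")
  expect_equal(g7$variant_count, 7L)
  expect_identical(nrow(call_snps(mk_profile("A", list(A = 5L, G = 10L)))), 0L)
  t1 <- call_snps(mk_profile("A", list(T = 1L)))
  expect_equal(t1$called_base, "T")

  # tie between two non-reference bases: no call, flagged ambiguous
  tie <- call_snps(mk_profile("A", list(G = 7L, T = 7L, A = 1L)))
  expect_identical(nrow(tie), 0L)
  expect_equal(attr(tie, "ambiguous"), 1L)

  # brute force over all count pairs <= 20 confirms the strict boundary
  for (r in 0:20) for (v in 0:20) {
    got <- nrow(call_snps(mk_profile("A", list(A = r, G = v)))) == 1
    expect_identical(got, v > 2 * r && v >= 1)
  }

  # scale-free in the factor: multiplying all counts changes no decisions
  set.seed(36)
  g <- generate_genome(50)
  p <- matrix(sample(0:20, 200, replace = TRUE), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  p1 <- structure(p, ref = g, class = c("alignment_profile", class(p)))
  p3 <- structure(p * 3L, ref = g, class = c("alignment_profile", class(p)))
  expect_identical(call_snps(p1)$position, call_snps(p3)$position)
  expect_identical(call_snps(p1)$called_base, call_snps(p3)$called_base)
})

test_that("spiked mutations are disjoint and reconstructible", {
  set.seed(37)
  g <- generate_genome(50000)
  sp <- spike_mutations(g, n = 100)
  expect_identical(nrow(sp$truth), 100L)
  o <- order(sp$truth$fp_start)
  expect_true(all(diff(sp$truth$fp_start[o]) > 0))
  expect_true(all(sp$truth$fp_end[o][-100] < sp$truth$fp_start[o][-1]))
  expect_identical(apply_mutations(g, sp$truth), sp$mutated_ref)

  snp_only <- spike_mutations(g, n = 1, type_mix = c(SNP = 1, insertion = 0,
                                                     deletion = 0))
  expect_identical(nchar(snp_only$mutated_ref), nchar(g))
  diffpos <- which(strsplit(snp_only$mutated_ref, "")[[1]] !=
                     strsplit(g, "")[[1]])
  expect_identical(diffpos, snp_only$truth$position)
  expect_false(snp_only$truth$alt == snp_only$truth$ref)

  expect_error(spike_mutations(generate_genome(100), n = 50), "too short")
})

test_that("detection scoring matches calls to footprints", {
  truth <- data.frame(type = rep("SNP", 10), position = 1:10 * 100,
                      ref = "A", alt = "G", fp_start = 1:10 * 100,
                      fp_end = 1:10 * 100)
  calls <- data.frame(position = 1:9 * 100)
  rep_ <- estimate_detection(truth, calls)
  expect_equal(rep_$per_type$fraction[rep_$per_type$type == "SNP"], 0.9)
  expect_equal(rep_$overall$fn_rate, 0.1)

  none <- estimate_detection(truth, data.frame(position = integer(0)))
  expect_equal(none$overall$fraction, 0)
})

test_that("no false positives arise from clean reads on the true reference", {
  set.seed(38)
  g <- generate_genome(4000)
  reads <- curate_reads(simulate_reads(g, coverage = 15))
  res <- align_iteratively(reads, g)
  calls <- call_snps(compile_profile(res$alignments, g), g)
  expect_identical(nrow(calls), 0L)
})

test_that("spike-in detection does not decrease with coverage", {
  set.seed(39)
  g <- generate_genome(6000)
  sp <- spike_mutations(g, n = 25, type_mix = c(SNP = 1, insertion = 0,
                                                deletion = 0))
  set.seed(40)
  all_reads <- curate_reads(simulate_reads(g, coverage = 30))
  frac <- vapply(c(5, 15, 30), function(cov) {
    # nested subsets: the 5x and 15x read sets are prefixes of the 30x set
    reads <- all_reads[seq_len(round(nrow(all_reads) * cov / 30)), ]
    res <- align_iteratively(reads, sp$mutated_ref)
    calls <- call_snps(compile_profile(res$alignments, sp$mutated_ref),
                       sp$mutated_ref)
    estimate_detection(sp$truth, calls)$overall$fraction
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[3], 0.9)
})
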