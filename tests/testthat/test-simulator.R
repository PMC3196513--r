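cfg <- function(...) sim_config(seed = 1, ...)

test_that("flask growth solves the multi-lineage census equation", {
  one <- new_lineages_for_test(1L, 0.6, 1e5)
  g <- grow_flask(one, 1e7)
  expect_equal(g$time_h, log(100) / 0.6, tolerance = 1e-9)
  expect_equal(sum(g$lineages$cell_count), 1e7)
  expect_equal(g$divisions, 1e7 - 1e5)

  # equal rates: final counts proportional to initial counts
  two <- new_lineages_for_test(1:2, c(0.5, 0.5), c(2e5, 1e5))
  g2 <- grow_flask(two, 3e7)
  expect_equal(g2$lineages$cell_count[1] / g2$lineages$cell_count[2], 2,
               tolerance = 1e-6)

  # unequal rates: harvest time matches an independent bisection oracle and
  # the faster lineage overtakes
  two2 <- new_lineages_for_test(1:2, c(0.6, 0.7), c(5e4, 5e4))
  g3 <- grow_flask(two2, 1e8)
  f <- function(t) 5e4 * exp(0.6 * t) + 5e4 * exp(0.7 * t) - 1e8
  lo <- 0; hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(g3$time_h, (lo + hi) / 2, tolerance = 1e-3 * 0.001)
  share <- g3$lineages$cell_count[2] / 1e8
  oracle_share <- 5e4 * exp(0.7 * g3$time_h) / 1e8
  expect_gt(share, 0.5)
  expect_equal(share, oracle_share, tolerance = 1e-3)

  expect_error(grow_flask(new_lineages_for_test(1L, 0, 100), 1000),
               "no growth")
})

test_that("mutant supply is binomial in divisions with multiplier linearity", {
  lin <- new_lineages_for_test(1L, 0.3, 2e6)
  no_mu <- cfg(mu_per_division = 0)
  set.seed(2)
  s0 <- seed_mutations(lin, 1e6, no_mu)
  expect_identical(nrow(s0$new), 0L)

  base <- cfg(mu_per_division = 1e-6)
  set.seed(3)
  counts <- replicate(1e4, nrow(seed_mutations(lin, 1e6, base)$new))
  expect_equal(mean(counts), 1.0, tolerance = 0.03)

  with_ntg <- cfg(mu_per_division = 1e-6, mutagen_multiplier = 10)
  set.seed(4)
  counts10 <- replicate(2e3, nrow(seed_mutations(lin, 1e6, with_ntg)$new))
  expect_equal(mean(counts10) / mean(counts), 10, tolerance = 0.1)

  # census is preserved: founders move out of the parent lineage
  set.seed(5)
  s <- seed_mutations(lin, 1e6, with_ntg)
  expect_equal(sum(s$lineages$cell_count), 2e6)
  expect_true(all(s$lineages$growth_rate <= with_ntg$gr_cap))
})

test_that("bottleneck is a multinomial sample that preserves totals", {
  single <- new_lineages_for_test(1L, 0.5, 1e6)
  set.seed(6)
  b <- bottleneck(single, 1e4)
  expect_equal(sum(b$cell_count), 1e4)
  expect_identical(nrow(b), 1L)

  several <- new_lineages_for_test(1:3, c(0.5, 0.5, 0.5), c(10, 20, 30))
  expect_identical(bottleneck(several, 60), several)
  expect_error(bottleneck(several, 0), "positive")

  # rare-lineage extinction matches the Poisson limit e^(-0.1)
  pair <- new_lineages_for_test(1:2, c(0.5, 0.5), c(1e9 - 1e3, 1e3))
  set.seed(7)
  gone <- replicate(2e3, {
    b <- bottleneck(pair, 1e5)
    !any(b$id == 2L)
  })
  expect_equal(mean(gone), exp(-0.1), tolerance = 0.03)
})

test_that("a supply-free evolution stays at the ancestral rate", {
  out <- simulate_evolution(cfg(mu_per_division = 0))
  expect_true(all(out$mean_gr == out$config$gr_initial))
  expect_equal(out$stabilization_flask, out$config$window)
  expect_identical(nrow(out$mutations), 0L)
})

test_that("emitted records conserve the internal division count exactly", {
  for (seed in c(1, 7, 42, 1234)) {
    out <- simulate_evolution(sim_config(seed = seed))
    res <- ccd_of_series(out$series)
    expect_identical(res$ccd, out$total_divisions)
    expect_equal(res$ccd, sum(out$series$final_cells - out$series$n0))
  }
})

test_that("identical config and seed reproduce the outcome bit for bit", {
  a <- simulate_evolution(sim_config(seed = 99))
  b <- simulate_evolution(sim_config(seed = 99))
  expect_identical(a, b)
})

test_that("aggregated first-bottleneck survival matches explicit sampling", {
  # Distributional equivalence of the two routes for mutant-pool survival:
  # (explicit) materialize M one-cell mutants and draw the full multinomial,
  # vs (aggregated) binomial pool survival then uniform slot assignment.
  resident <- 1e5; M <- 50L; transfer <- 1e4
  set.seed(8)
  explicit <- replicate(3e3, {
    counts <- as.numeric(rmultinom(1, transfer, c(resident, rep(1, M))))
    sum(counts[-1])
  })
  set.seed(9)
  aggregated <- replicate(3e3, {
    rbinom(1, transfer, M / (resident + M))
  })
  expect_equal(mean(explicit), mean(aggregated), tolerance = 0.05)
  expect_equal(var(explicit), var(aggregated), tolerance = 0.1)
  expect_gt(suppressWarnings(
    stats::ks.test(explicit, aggregated)$p.value), 0.01)
})

test_that("selection enriches large-effect mutations among fixed ones", {
  fixed_effects <- unlist(lapply(1:50, function(s) {
    out <- simulate_evolution(sim_config(seed = 5000 + s))
    m <- out$mutations
    m$effect[m$final_frequency > 0.5]
  }))
  expect_gt(length(fixed_effects), 10)
  expect_gt(mean(fixed_effects), 0.03)
})

test_that("random genomes have the requested composition and determinism", {
  set.seed(10)
  g <- generate_genome(1e4, gc = 0.5)
  gc <- mean(strsplit(g, "")[[1]] %in% c("G", "C"))
  expect_equal(gc, 0.5, tolerance = 0.04)
  expect_error(generate_genome(0), ">= 1")
  set.seed(123); g1 <- generate_genome(500)
  set.seed(123); g2 <- generate_genome(500)
  expect_identical(g1, g2)
})

test_that("simulated reads match the genome up to the error model", {
  set.seed(12)
  g <- generate_genome(2000)
  reads <- simulate_reads(g, coverage = 2, read_length = 36)
  expect_equal(nrow(reads), round(2 * 2000 / 36))
  for (i in sample(nrow(reads), 10)) {
    sub <- substring(g, reads$true_start[i], reads$true_start[i] + 35)
    if (reads$true_strand[i] == "-") {
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    }
    expect_identical(reads$bases[i], sub)
  }

  set.seed(13)
  noisy <- simulate_reads(g, coverage = 10, error_rate = 0.01)
  mism <- vapply(seq_len(nrow(noisy)), function(i) {
    sub <- substring(g, noisy$true_start[i], noisy$true_start[i] + 35)
    if (noisy$true_strand[i] == "-") {
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    }
    sum(strsplit(noisy$bases[i], "")[[1]] != strsplit(sub, "")[[1]])
  }, numeric(1))
  expect_equal(mean(mism) / 36, 0.01, tolerance = 0.2)
  expect_error(simulate_reads(g, coverage = 0), "positive")
})
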