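#' Configuration for the serial-passage evolution simulator
#'
#' The simulator propagates a lineage-structured population through daily
#' grow/mutate/record/bottleneck cycles. Mutations arise in proportion to the
#' number of cell divisions; a mutagen multiplies the per-division beneficial
#' mutation probability. Defaults describe a glycerol-like evolution in
#' 200 ml of minimal medium: flasks are grown to a final OD600 near 0.7
#' (about 1.1e10 cells at 7.87e10 cells/L/OD) from inocula of 2.5e4 to 1.2e6
#' cells, giving roughly 14-19 generations per flask.
#'
#' @param mu_per_division Probability that a cell division yields a beneficial
#'   mutant that is seeded as a new single-cell lineage at the end of growth
#'   (default 3e-5). This is an effective supply rate: seeding mutants as
#'   single cells at passage time omits the within-flask amplification of
#'   mutants arising early in growth, so the rate folds that amplification
#'   in. It is calibrated once so that the default (no-mutagen) condition
#'   climbs quasi-continuously to the growth-rate cap and stabilizes after
#'   roughly 25-35 flasks, the timescale of real glycerol evolutions.
#' @param mutagen_multiplier Factor >= 1 multiplying `mu_per_division`
#'   (default 1; continuous non-toxic NTG exposure is modelled as 10).
#' @param effect_size_mean Mean of the exponential distribution of additive
#'   growth-rate gains, h^-1 (default 0.03).
#' @param gr_initial Ancestral growth rate, h^-1 (default 0.25).
#' @param gr_cap Maximum attainable growth rate, h^-1 (default 0.64, the
#'   stable endpoint phenotype).
#' @param transfer_count_range Range of cells transferred at each passage;
#'   drawn log-uniformly (default c(2.5e4, 1.2e6)).
#' @param final_od_range Per-flask final OD600 target interval, drawn
#'   uniformly (default c(0.6, 0.8)).
#' @param volume Culture volume in litres (default 0.2).
#' @param conversion Cells per litre per OD600 (default 7.87e10).
#' @param max_flasks Hard cap on the number of passages (default 60).
#' @param window,rel_tol Stabilization rule parameters
#'   (see [detect_stabilization()]).
#' @param seed Integer seed; mandatory (the simulation is fully reproducible
#'   given config + seed).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(mu_per_division = 3e-5,
                       mutagen_multiplier = 1,
                       effect_size_mean = 0.03,
                       gr_initial = 0.25,
                       gr_cap = 0.64,
                       transfer_count_range = c(2.5e4, 1.2e6),
                       final_od_range = c(0.6, 0.8),
                       volume = 0.2,
                       conversion = 7.87e10,
                       max_flasks = 60,
                       window = 10,
                       rel_tol = 0.05,
                       seed = NULL) {
  stopifnot(mu_per_division >= 0, mu_per_division <= 1,
            mutagen_multiplier >= 1,
            effect_size_mean > 0,
            gr_initial > 0, gr_initial <= gr_cap,
            length(transfer_count_range) == 2,
            transfer_count_range[1] >= 1,
            diff(transfer_count_range) >= 0,
            length(final_od_range) == 2, final_od_range[1] > 0,
            volume > 0, conversion > 0, max_flasks >= 1)
  if (is.null(seed)) stop("sim_config requires an explicit integer seed")
  structure(list(
    mu_per_division = mu_per_division,
    mutagen_multiplier = mutagen_multiplier,
    effect_size_mean = effect_size_mean,
    gr_initial = gr_initial,
    gr_cap = gr_cap,
    transfer_count_range = transfer_count_range,
    final_od_range = final_od_range,
    volume = volume,
    conversion = conversion,
    max_flasks = as.integer(max_flasks),
    window = as.integer(window),
    rel_tol = rel_tol,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Lineage table used internally: data.frame(id, growth_rate, cell_count).
new_lineages <- function(id, growth_rate, cell_count) {
  data.frame(id = id, growth_rate = growth_rate, cell_count = cell_count)
}

# Largest-remainder apportionment of `total` among non-negative weights.
apportion <- function(weights, total) {
  if (total == 0) return(rep(0, length(weights)))
  exact <- weights / sum(weights) * total
  base <- floor(exact)
  short <- round(total - sum(base))
  if (short > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Grow a flask of lineages to a target census
#'
#' Growth within a flask is deterministic exponential: the flask is harvested
#' at the time T solving `sum_j n_j * exp(r_j * T) = target_total`, and each
#' lineage scales to `n_j * exp(r_j * T)`, rounded by largest-remainder
#' apportionment so the total is exactly `target_total`.
#'
#' @param lineages Lineage table (data.frame with columns `id`,
#'   `growth_rate`, `cell_count`).
#' @param target_total Target census (> current total).
#' @return A list with `lineages` (grown counts), `divisions` (per-lineage
#'   final - initial) and `time_h` (the harvest time).
#' @export
grow_flask <- function(lineages, target_total) {
  n0 <- lineages$cell_count
  r <- lineages$growth_rate
  total0 <- sum(n0)
  stopifnot(total0 >= 1, target_total > total0)
  if (all(r <= 0)) stop("no growth: all lineage growth rates are zero")
  f <- function(t) sum(n0 * exp(r * t)) - target_total
  upper <- log(target_total / total0) / max(r) + 1
  while (f(upper) < 0) upper <- upper * 2
  t_star <- stats::uniroot(f, c(0, upper), tol = 1e-12)$root
  grown <- apportion(n0 * exp(r * t_star), target_total)
  out <- lineages
  out$cell_count <- grown
  list(lineages = out, divisions = grown - n0, time_h = t_star)
}

#' Seed beneficial mutants in proportion to cell divisions
#'
#' Each lineage contributes `Binomial(divisions, mu * multiplier)` new
#' mutants (the Poisson limit is used when the division count exceeds the
#' 32-bit integer range; in the regime simulated, `divisions * mu << sqrt(divisions)`,
#' the two are indistinguishable). Every mutant founds a new lineage of one
#' cell whose growth rate is the parent's plus an exponential gain, capped at
#' `gr_cap`; the founding cell is moved out of the parent lineage, so the
#' census is unchanged and division bookkeeping stays exact.
#'
#' @param lineages Lineage table after growth.
#' @param divisions Per-lineage division counts from [grow_flask()].
#' @param config A [sim_config()].
#' @param next_id First unused lineage id.
#' @return A list with `lineages` (parents plus new mutant lineages) and
#'   `new` (data.frame of the mutants: id, parent, growth_rate).
#' @export
seed_mutations <- function(lineages, divisions, config, next_id = max(lineages$id) + 1L) {
  stopifnot(all(divisions >= 0))
  p <- config$mu_per_division * config$mutagen_multiplier
  k <- vapply(divisions, function(d) {
    if (d == 0 || p == 0) return(0)
    if (d < 2^31) rbinom(1, as.integer(d), p) else rpois(1, d * p)
  }, numeric(1))
  # cannot move more founders out of a lineage than it has cells
  k <- pmin(k, lineages$cell_count)
  total_new <- sum(k)
  if (total_new == 0) {
    return(list(lineages = lineages,
                new = data.frame(id = integer(), parent = integer(),
                                 growth_rate = numeric())))
  }
  parent_idx <- rep(seq_len(nrow(lineages)), times = k)
  gains <- rexp(total_new, rate = 1 / config$effect_size_mean)
  gr_new <- pmin(lineages$growth_rate[parent_idx] + gains, config$gr_cap)
  ids <- seq.int(next_id, length.out = total_new)
  lineages$cell_count <- lineages$cell_count - k
  out <- rbind(lineages,
               new_lineages(ids, gr_new, rep(1, total_new)))
  list(lineages = out,
       new = data.frame(id = ids, parent = lineages$id[parent_idx],
                        growth_rate = gr_new))
}

#' Serial-dilution bottleneck
#'
#' Transfers `transfer_count` cells into fresh medium by multinomial sampling
#' with probabilities proportional to lineage counts; lineages sampled to
#' zero are dropped (extinct).
#'
#' @param lineages Lineage table.
#' @param transfer_count Number of cells transferred (1 <= transfer_count <=
#'   total census).
#' @return The sampled lineage table.
#' @export
bottleneck <- function(lineages, transfer_count) {
  if (transfer_count <= 0) stop("transfer_count must be positive")
  total <- sum(lineages$cell_count)
  stopifnot(transfer_count <= total)
  if (transfer_count == total) return(lineages)
  counts <- as.numeric(rmultinom(1, size = transfer_count,
                                 prob = lineages$cell_count))
  keep <- counts > 0
  out <- lineages[keep, , drop = FALSE]
  out$cell_count <- counts[keep]
  rownames(out) <- NULL
  out
}

#' Simulate a serial-passage evolution experiment
#'
#' Iterates grow -> mutate -> record -> bottleneck from a clonal ancestral
#' population until the growth-rate stabilization rule fires or `max_flasks`
#' is reached. Stabilization is only considered once the population mean
#' growth rate has improved over the ancestor by more than `rel_tol`
#' (an experiment is not ended before any adaptation has been observed).
#' The emitted passage records carry exact cell counts alongside the OD600
#' readings, so the internal division tally and [ccd_of_series()] agree
#' exactly.
#'
#' Freshly seeded mutants (single cells at the moment of passage) are carried
#' through their first bottleneck by an aggregated two-stage sample that is
#' distribution-identical to materializing each one-cell lineage and drawing
#' the full multinomial of [bottleneck()]: the mutant pool survives as
#' `Binomial(transfer, M/N)` cells, which are then assigned to individual
#' mutants (and thence parents) uniformly at random. Effect sizes are drawn
#' only for mutants that survive; the reported mutation history therefore
#' lists mutations that outlived their first bottleneck, alongside the total
#' mutation supply.
#'
#' @param config A [sim_config()] (its `seed` drives all randomness).
#' @return A list of class `sim_outcome` with elements `series` (an
#'   [evolution_series()]), `mean_gr` (true population-mean growth rate per
#'   flask), `mutations` (data.frame: id, parent, flask_of_origin, effect
#'   growth rate, final count and frequency), `mutation_supply` (total
#'   mutants seeded across the run), `total_divisions`,
#'   `stabilization_flask` (NA if `max_flasks` was hit first) and `config`.
#' @export
simulate_evolution <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lineages <- new_lineages(1L, config$gr_initial, NA_real_)
  tr <- config$transfer_count_range
  draw_transfer <- function() {
    round(exp(runif(1, log(tr[1]), log(tr[2]))))
  }
  lineages$cell_count <- draw_transfer()

  n0 <- final_cells <- final_od <- mean_gr <- numeric(0)
  muts <- data.frame(id = integer(), parent = integer(),
                     flask_of_origin = integer(), growth_rate = numeric(),
                     effect = numeric())
  total_divisions <- 0
  mutation_supply <- 0
  next_id <- 2L
  stab <- NA_integer_
  p <- config$mu_per_division * config$mutagen_multiplier

  for (flask in seq_len(config$max_flasks)) {
    n0_this <- sum(lineages$cell_count)
    od_target <- runif(1, config$final_od_range[1], config$final_od_range[2])
    target <- round(cells_from_od(od_target, config$volume, config$conversion))

    g <- grow_flask(lineages, target)
    total_divisions <- total_divisions + sum(g$divisions)
    lineages <- g$lineages

    # mutation supply in proportion to this flask's divisions: each mutant is
    # one daughter cell of an already-counted division, moved into a pool of
    # single-cell mutants awaiting the bottleneck
    k <- vapply(g$divisions, function(d) {
      if (d == 0 || p == 0) return(0)
      if (d < 2^31) rbinom(1, as.integer(d), p) else rpois(1, d * p)
    }, numeric(1))
    k <- pmin(k, lineages$cell_count)
    lineages$cell_count <- lineages$cell_count - k
    pool <- sum(k)
    mutation_supply <- mutation_supply + pool

    census <- sum(lineages$cell_count) + pool   # == target by construction
    n0 <- c(n0, n0_this)
    final_cells <- c(final_cells, census)
    final_od <- c(final_od, census / (config$volume * config$conversion))
    mean_gr <- c(mean_gr,
                 (sum(lineages$growth_rate * lineages$cell_count) +
                    sum(lineages$growth_rate * k)) / census)

    # the plateau rule is armed once adaptation has been observed; when the
    # mutation supply is zero no adaptation is possible and the rule applies
    # as literally stated
    improved <- p == 0 ||
      mean_gr[flask] > config$gr_initial * (1 + config$rel_tol)
    if (improved && flask >= config$window) {
      probe <- evolution_series(n0 = n0, final_cells = final_cells,
                                growth_rate = mean_gr)
      stab <- detect_stabilization(probe, window = config$window,
                                   rel_tol = config$rel_tol)
      if (!is.na(stab)) break
    }

    if (flask < config$max_flasks) {
      transfer <- draw_transfer()
      # multinomial bottleneck over established lineages + the mutant pool
      counts <- as.numeric(rmultinom(1, size = transfer,
                                     prob = c(lineages$cell_count, pool)))
      surv <- counts[length(counts)]
      counts <- counts[-length(counts)]
      keep <- counts > 0
      parents <- lineages       # row-aligned with k, for survivor assignment
      lineages <- lineages[keep, , drop = FALSE]
      lineages$cell_count <- counts[keep]
      rownames(lineages) <- NULL
      if (surv > 0) {
        # assign surviving pool cells to individual mutants uniformly (with
        # coalescence), then mutants to parents by their supply shares
        slots <- sample.int(pool, surv, replace = TRUE)
        mult <- table(slots)
        slot_id <- as.numeric(names(mult))
        parent_idx <- findInterval(slot_id - 0.5, cumsum(k)) + 1L
        gains <- rexp(length(slot_id), rate = 1 / config$effect_size_mean)
        gr_new <- pmin(parents$growth_rate[parent_idx] + gains, config$gr_cap)
        ids <- seq.int(next_id, length.out = length(slot_id))
        next_id <- next_id + length(slot_id)
        muts <- rbind(muts, data.frame(id = ids,
                                       parent = parents$id[parent_idx],
                                       flask_of_origin = flask,
                                       growth_rate = gr_new,
                                       effect = gr_new -
                                         parents$growth_rate[parent_idx]))
        lineages <- rbind(lineages,
                          new_lineages(ids, gr_new, as.numeric(mult)))
      }
    }
  }

  series <- evolution_series(n0 = n0, final_od = final_od,
                             final_cells = final_cells, growth_rate = mean_gr,
                             condition = "simulated",
                             mutagen = config$mutagen_multiplier > 1)
  final_counts <- setNames(lineages$cell_count, lineages$id)
  if (nrow(muts) > 0) {
    muts$final_count <- as.numeric(final_counts[as.character(muts$id)])
    muts$final_count[is.na(muts$final_count)] <- 0
    muts$final_frequency <- muts$final_count / sum(lineages$cell_count)
  } else {
    muts$final_count <- numeric(0)
    muts$final_frequency <- numeric(0)
  }
  structure(list(series = series, mean_gr = mean_gr, mutations = muts,
                 mutation_supply = mutation_supply,
                 total_divisions = total_divisions,
                 stabilization_flask = stab, config = config),
            class = "sim_outcome")
}

#' @export
print.sim_outcome <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_outcome> %d flasks | final mean GR %.3f h^-1 | ",
           "total divisions %.3g | stabilized at %s\n"),
    nrow(x$series), utils::tail(x$mean_gr, 1), x$total_divisions,
    ifelse(is.na(x$stabilization_flask), "never",
           as.character(x$stabilization_flask))))
  invisible(x)
}
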