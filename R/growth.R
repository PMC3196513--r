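#' Construct a growth curve
#'
#' @param time_h Sampling times in hours, strictly increasing.
#' @param od600 OD600 readings, all > 0.
#' @return A data.frame of class `growth_curve`.
#' @export
growth_curve <- function(time_h, od600) {
  stopifnot(length(time_h) == length(od600))
  if (any(diff(time_h) <= 0)) stop("time_h must be strictly increasing")
  if (any(od600 <= 0)) stop("od600 must be strictly positive")
  structure(data.frame(time_h = time_h, od600 = od600),
            class = c("growth_curve", "data.frame"))
}

#' Estimate exponential growth rate from a growth curve
#'
#' The growth rate is the ordinary least-squares slope of `ln(OD600)` against
#' time (hours), restricted to readings inside the exponential window
#' `od_min < OD600 < od_max` (open interval). Points outside the window are
#' excluded, not truncated.
#'
#' @param curve A [growth_curve()] or a data.frame with columns `time_h`,
#'   `od600`.
#' @param od_min,od_max Open-interval OD600 window bounds
#'   (defaults 0.05 and 0.3).
#' @return Growth rate in h^-1.
#' @export
fit_growth_rate <- function(curve, od_min = 0.05, od_max = 0.3) {
  stopifnot(all(c("time_h", "od600") %in% names(curve)))
  inside <- curve$od600 > od_min & curve$od600 < od_max
  if (sum(inside) < 3) {
    stop("insufficient data: need >= 3 points with ", od_min,
         " < OD600 < ", od_max, " (have ", sum(inside), ")")
  }
  fit <- lm(log(od600) ~ time_h, data = curve[inside, , drop = FALSE])
  unname(coef(fit)[["time_h"]])
}

#' Detect growth-rate stabilization in an evolution series
#'
#' An evolution is considered stabilized at the earliest flask `j >= window`
#' such that, over the trailing `window` flasks, (i) the relative range of the
#' recorded growth rates, `(max - min) / mean`, is at most `rel_tol`, and
#' (ii) the least-squares slope of growth rate against flask index does not
#' exceed a drift allowance of `rel_tol * mean / window` per flask (i.e. the
#' fitted drift across the whole window stays within `rel_tol` of the mean).
#' This makes the experimentalist's "no significant change over the previous
#' ten flasks" rule deterministic and testable.
#'
#' @param series An [evolution_series()] with `growth_rate` recorded for
#'   every flask.
#' @param window Number of trailing flasks examined (default 10).
#' @param rel_tol Relative tolerance on the window's growth-rate range
#'   (default 0.05).
#' @return The 1-based flask index at which stabilization is first met, or
#'   `NA_integer_` if it never is.
#' @export
detect_stabilization <- function(series, window = 10, rel_tol = 0.05) {
  stopifnot(inherits(series, "evolution_series"))
  gr <- series$growth_rate
  if (anyNA(gr)) stop("growth_rate must be recorded for every flask")
  m <- length(gr)
  if (window > m) stop("window (", window, ") exceeds series length (", m, ")")
  idx <- seq_len(window)
  for (j in window:m) {
    w <- gr[(j - window + 1):j]
    mu <- mean(w)
    if ((max(w) - min(w)) / mu > rel_tol) next
    slope <- coef(lm(w ~ idx))[["idx"]]
    if (slope <= rel_tol * mu / window) return(series$flask_index[j])
  }
  NA_integer_
}

#' Summarize replicate evolutions of one condition
#'
#' Builds a condition-level summary in the style of an ALE endpoint table:
#' the mean and SD of the stable growth rate (pooling, from each replicate,
#' the endpoint and the previous two recorded growth rates, i.e. the last
#' three non-missing values), and the mean and SD across replicates of the
#' cumulative generations and CCD accumulated up to each replicate's
#' stabilization flask. Replicates that never stabilize are excluded from the
#' generation/CCD averages with a warning.
#'
#' @param replicates A list of [evolution_series()] objects (one condition).
#' @param constants [calibration_constants()].
#' @param window,rel_tol Passed to [detect_stabilization()].
#' @return A list of class `condition_summary` with fields `condition`,
#'   `mutagen`, `n_replicates`, `replicate_labels`, `mean_gr`, `sd_gr`,
#'   `mean_generations`, `sd_generations`, `mean_ccd`, `sd_ccd` and
#'   `stabilization_flask` (per replicate, NA where never reached).
#' @export
summarize_condition <- function(replicates,
                                constants = calibration_constants(),
                                window = 10, rel_tol = 0.05) {
  stopifnot(is.list(replicates), length(replicates) >= 1,
            all(vapply(replicates, inherits, logical(1), "evolution_series")))
  labels <- names(replicates)
  if (is.null(labels)) labels <- sprintf("rep%d", seq_along(replicates))

  last3 <- lapply(replicates, function(s) {
    gr <- s$growth_rate[!is.na(s$growth_rate)]
    if (length(gr) < 3) {
      stop("each replicate needs at least 3 recorded growth rates")
    }
    utils::tail(gr, 3)
  })
  pooled <- unlist(last3)

  stab <- vapply(replicates, function(s) {
    if (anyNA(s$growth_rate)) NA_integer_
    else detect_stabilization(s, window = window, rel_tol = rel_tol)
  }, integer(1))
  ok <- !is.na(stab)
  if (!all(ok)) {
    warning("replicate(s) ", paste(labels[!ok], collapse = ", "),
            " never stabilized; excluded from generation/CCD averages")
  }

  gens <- ccds <- rep(NA_real_, length(replicates))
  for (i in which(ok)) {
    s <- replicates[[i]]
    upto <- s[s$flask_index <= stab[i], , drop = FALSE]
    attributes(upto)[c("condition", "mutagen", "class")] <-
      attributes(s)[c("condition", "mutagen", "class")]
    res <- ccd_of_series(upto, constants)
    gens[i] <- res$cumulative_generations
    ccds[i] <- res$ccd
  }

  sd0 <- function(x) if (length(x) <= 1) 0 else sd(x)
  structure(list(
    condition = attr(replicates[[1]], "condition"),
    mutagen = attr(replicates[[1]], "mutagen"),
    n_replicates = length(replicates),
    replicate_labels = labels,
    mean_gr = mean(pooled),
    sd_gr = sd0(pooled),
    mean_generations = mean(gens[ok]),
    sd_generations = sd0(gens[ok]),
    mean_ccd = mean(ccds[ok]),
    sd_ccd = sd0(ccds[ok]),
    stabilization_flask = setNames(stab, labels)
  ), class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<condition_summary> '%s'%s, %d replicate(s)\n",
           "  growth rate  %.3f +/- %.3f h^-1\n",
           "  generations  %.0f +/- %.0f\n",
           "  CCD          %.3g +/- %.2g\n"),
    x$condition, if (isTRUE(x$mutagen)) " (+NTG)" else "",
    x$n_replicates, x$mean_gr, x$sd_gr,
    x$mean_generations, x$sd_generations, x$mean_ccd, x$sd_ccd))
  invisible(x)
}

#' Condition summary table across conditions
#'
#' @param summaries A list of `condition_summary` objects.
#' @return A data.frame with one row per condition, mirroring the columns of
#'   an ALE endpoint table (growth rate, generations, CCD, each +/- SD).
#' @export
condition_table <- function(summaries) {
  stopifnot(all(vapply(summaries, inherits, logical(1), "condition_summary")))
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(condition = s$condition, mutagen = s$mutagen,
               n_replicates = s$n_replicates,
               mean_gr = s$mean_gr, sd_gr = s$sd_gr,
               mean_generations = s$mean_generations,
               sd_generations = s$sd_generations,
               mean_ccd = s$mean_ccd, sd_ccd = s$sd_ccd)
  }))
}
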