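#' Calibration constants for OD600-to-cell-count conversion
#'
#' Cultures are tracked by optical density at 600 nm; cell counts are obtained
#' by a linear conversion calibrated separately for populations evolved with
#' and without the mutagen NTG (the mutagen changes cell morphology and hence
#' the OD-per-cell relationship).
#'
#' @param cells_per_liter_per_od_no_mutagen Cells per litre per OD600 unit for
#'   mutagen-free cultures (default 7.87e10).
#' @param cells_per_liter_per_od_mutagen Cells per litre per OD600 unit for
#'   NTG-exposed cultures (default 2.32e10).
#' @param culture_volume Culture volume in litres (default 0.2, i.e. 200 ml).
#' @return An object of class `calibration_constants`.
#' @export
#' @examples
#' const <- calibration_constants()
#' cells_from_od(0.71, const$culture_volume,
#'               const$cells_per_liter_per_od_no_mutagen)
calibration_constants <- function(cells_per_liter_per_od_no_mutagen = 7.87e10,
                                  cells_per_liter_per_od_mutagen = 2.32e10,
                                  culture_volume = 0.2) {
  stopifnot(cells_per_liter_per_od_no_mutagen > 0,
            cells_per_liter_per_od_mutagen > 0,
            culture_volume > 0)
  structure(list(
    cells_per_liter_per_od_no_mutagen = cells_per_liter_per_od_no_mutagen,
    cells_per_liter_per_od_mutagen = cells_per_liter_per_od_mutagen,
    culture_volume = culture_volume
  ), class = "calibration_constants")
}

#' Convert an OD600 reading to a cell count
#'
#' @param od600 Optical density at 600 nm (dimensionless, > 0).
#' @param volume Culture volume in litres (> 0).
#' @param conversion Calibrated cells per litre per OD600 unit (> 0).
#' @return Estimated number of cells in the culture.
#' @export
cells_from_od <- function(od600, volume, conversion) {
  if (any(od600 <= 0) || any(volume <= 0) || any(conversion <= 0)) {
    stop("od600, volume and conversion must all be strictly positive")
  }
  od600 * volume * conversion
}

#' Generations elapsed in one flask
#'
#' Assuming exponential growth by binary fission and a negligible death rate,
#' a culture growing from `n0` to `n_final` cells undergoes
#' `log2(n_final / n0)` population doublings. Non-integer values are
#' meaningful and returned unrounded.
#'
#' @param n0 Initial (inoculum) cell count, >= 1.
#' @param n_final Final cell count at passage, >= `n0`.
#' @return Number of generations (real-valued).
#' @export
generations_per_flask <- function(n0, n_final) {
  if (any(n0 < 1)) stop("n0 must be >= 1")
  if (any(n_final < n0)) stop("n_final must be >= n0 (shrinking culture)")
  log2(n_final / n0)
}

#' Cell divisions elapsed in one flask
#'
#' Under binary fission every division increases the census by exactly one
#' cell, so the number of divisions in a flask is `n_final - n0`, identically
#' `n0 * (2^n - 1)` with `n = generations_per_flask(n0, n_final)`.
#'
#' @inheritParams generations_per_flask
#' @return Number of cell divisions.
#' @export
divisions_per_flask <- function(n0, n_final) {
  if (any(n0 < 1)) stop("n0 must be >= 1")
  if (any(n_final < n0)) stop("n_final must be >= n0 (shrinking culture)")
  n_final - n0
}

#' Construct an evolution series from per-flask passage records
#'
#' An evolution series is the ordered record of one serial-passage evolution:
#' one row per flask with the inoculum size, the final OD600 and/or final cell
#' count, and optionally a measured growth rate.
#'
#' @param flask_index Strictly increasing 1-based flask indices.
#' @param n0 Initial cell count per flask (>= 1).
#' @param final_od Final OD600 per flask (NA allowed when `final_cells` given).
#' @param final_cells Final cell count per flask (NA allowed when `final_od`
#'   given; takes precedence over `final_od` when both are present).
#' @param growth_rate Optional measured growth rates (h^-1), NA where not
#'   recorded.
#' @param condition Condition label (e.g. carbon source).
#' @param mutagen Logical flag: evolved under continuous NTG exposure?
#' @return An object of class `evolution_series` (a data.frame with
#'   attributes `condition` and `mutagen`).
#' @export
evolution_series <- function(flask_index = seq_along(n0), n0,
                             final_od = NA_real_, final_cells = NA_real_,
                             growth_rate = NA_real_,
                             condition = "unspecified", mutagen = FALSE) {
  m <- length(n0)
  df <- data.frame(
    flask_index = as.integer(flask_index),
    n0 = as.numeric(n0),
    final_od = rep_len(as.numeric(final_od), m),
    final_cells = rep_len(as.numeric(final_cells), m),
    growth_rate = rep_len(as.numeric(growth_rate), m)
  )
  if (m == 0) stop("an evolution series needs at least one record")
  if (any(diff(df$flask_index) <= 0)) {
    stop("flask_index must be strictly increasing")
  }
  if (any(df$n0 < 1)) stop("n0 must be >= 1 in every record")
  bad_od <- !is.na(df$final_od) & df$final_od <= 0
  if (any(bad_od)) stop("final_od must be > 0 where present")
  structure(df, condition = condition, mutagen = isTRUE(mutagen),
            class = c("evolution_series", "data.frame"))
}

#' @export
print.evolution_series <- function(x, ...) {
  cat(sprintf("<evolution_series> %d flasks, condition '%s'%s\n",
              nrow(x), attr(x, "condition"),
              if (isTRUE(attr(x, "mutagen"))) " (+NTG)" else ""))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more flasks\n", nrow(x) - 6L))
  invisible(x)
}

# Resolve each record's final cell count: stored count preferred, otherwise
# converted from final_od via the condition-appropriate constant.
resolve_final_cells <- function(series, constants) {
  conv <- if (isTRUE(attr(series, "mutagen"))) {
    constants$cells_per_liter_per_od_mutagen
  } else {
    constants$cells_per_liter_per_od_no_mutagen
  }
  n_final <- series$final_cells
  need <- is.na(n_final)
  if (any(need & is.na(series$final_od))) {
    stop("records ", paste(series$flask_index[need & is.na(series$final_od)],
                           collapse = ", "),
         " have neither final_cells nor final_od")
  }
  n_final[need] <- cells_from_od(series$final_od[need],
                                 constants$culture_volume, conv)
  n_final
}

#' Cumulative cell divisions and generations of an evolution series
#'
#' Sums per-flask divisions (`N_i - N_{0,i}`) and per-flask generations
#' (`log2(N_i / N_{0,i})`) over all `m` flasks of a serial-passage evolution.
#' The cumulative division count (CCD) is the experiment's timescale: it
#' counts every binary-fission event, and therefore every opportunity for a
#' replication-coupled mutation, across the whole evolution.
#'
#' @param series An [evolution_series()].
#' @param constants [calibration_constants()] used to convert OD600 readings
#'   for records lacking an explicit final cell count. The mutagen flag of the
#'   series selects which conversion constant applies.
#' @return A list of class `ccd_result` with elements
#'   `per_flask_generations`, `per_flask_divisions`,
#'   `cumulative_generations` and `ccd`.
#' @export
#' @examples
#' glycerol <- evolution_series(n0 = rep(8.5e4, 35), final_od = rep(0.71, 35),
#'                              condition = "glycerol")
#' ccd_of_series(glycerol)  # ~595 generations, ~3.9e11 divisions
ccd_of_series <- function(series, constants = calibration_constants()) {
  stopifnot(inherits(series, "evolution_series"))
  n_final <- resolve_final_cells(series, constants)
  gens <- generations_per_flask(series$n0, n_final)
  divs <- divisions_per_flask(series$n0, n_final)
  structure(list(
    per_flask_generations = gens,
    per_flask_divisions = divs,
    cumulative_generations = sum(gens),
    ccd = sum(divs)
  ), class = "ccd_result")
}

#' @export
print.ccd_result <- function(x, ...) {
  cat(sprintf(
    "<ccd_result> %d flasks | cumulative generations %.1f | CCD %.3g\n",
    length(x$per_flask_divisions), x$cumulative_generations, x$ccd))
  invisible(x)
}
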