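#' Subtract per-experiment background from well signals
#'
#' Medium-only (blank) wells define the background luminescence of each
#' experiment; their mean is subtracted from every other well of the same
#' experiment and the blank rows are dropped from the output.
#'
#' @param measurements Well-level measurement table
#'   (see [validate_measurements()]).
#' @param design The matching design table.
#' @return The corrected measurement tibble without blank rows.
#' @export
background_correct <- function(measurements, design) {
  design <- validate_design(design)
  measurements <- validate_measurements(measurements, design)
  blank_ids <- design$condition_id[design$role == "blank"]
  control_ids <- design$condition_id[design$role == "untreated_control"]
  is_blank <- measurements$condition_id %in% blank_ids
  blank_means <- measurements[is_blank, ] |>
    dplyr::group_by(.data$experiment) |>
    dplyr::summarise(.blank = mean(.data$signal), .groups = "drop")
  no_blank <- setdiff(unique(measurements$experiment), blank_means$experiment)
  if (length(no_blank) > 0) {
    input_error(paste0("experiment(s) without blank wells: ",
                       paste(no_blank, collapse = ", ")))
  }
  out <- measurements[!is_blank, ] |>
    dplyr::left_join(blank_means, by = "experiment") |>
    dplyr::mutate(signal = .data$signal - .data$.blank) |>
    dplyr::select(-".blank")
  ctrl <- out[out$condition_id %in% control_ids, ] |>
    dplyr::group_by(.data$experiment) |>
    dplyr::summarise(m = mean(.data$signal), .groups = "drop")
  if (any(ctrl$m <= 0)) {
    input_error(paste0("background-corrected control mean is nonpositive in ",
                       "experiment(s): ",
                       paste(ctrl$experiment[ctrl$m <= 0], collapse = ", "),
                       " (uninterpretable plate)"))
  }
  out
}

#' Compute per-experiment survival fractions
#'
#' Within each independent experiment, the survival fraction (SF) of a
#' condition is its mean background-corrected signal divided by the mean
#' untreated-control signal of the same experiment. Statistics downstream
#' are taken across experiments, never across pooled wells, so the
#' experiment is the unit of replication.
#'
#' @param measurements Background-corrected measurements
#'   (see [background_correct()]; blank rows must already be removed).
#' @param design The matching design table.
#' @param sf_floor Optional positive floor applied to nonpositive SFs so the
#'   log transform stays defined. `NULL` (default) makes a nonpositive SF an
#'   error naming the condition.
#' @return A tibble with one row per condition and experiment:
#'   `condition_id`, `role`, `experiment`, `sf`.
#' @export
survival_fraction <- function(measurements, design, sf_floor = NULL) {
  design <- validate_design(design)
  measurements <- validate_measurements(measurements, design)
  blank_ids <- design$condition_id[design$role == "blank"]
  if (any(measurements$condition_id %in% blank_ids)) {
    input_error("blank rows present; run background_correct() first")
  }
  control_ids <- design$condition_id[design$role == "untreated_control"]
  means <- measurements |>
    dplyr::group_by(.data$condition_id, .data$experiment) |>
    dplyr::summarise(m = mean(.data$signal), .groups = "drop")
  ctrl <- means |>
    dplyr::filter(.data$condition_id %in% control_ids) |>
    dplyr::group_by(.data$experiment) |>
    dplyr::summarise(control_mean = mean(.data$m), .groups = "drop")
  sf <- means |>
    dplyr::left_join(ctrl, by = "experiment") |>
    dplyr::mutate(sf = .data$m / .data$control_mean) |>
    dplyr::select("condition_id", "experiment", "sf")
  if (any(sf$sf <= 0)) {
    bad <- unique(sf$condition_id[sf$sf <= 0])
    if (is.null(sf_floor)) {
      input_error(paste0("nonpositive survival fraction for condition(s): ",
                         paste(bad, collapse = ", "),
                         "; set sf_floor to floor them instead"))
    }
    if (sf_floor <= 0) input_error("sf_floor must be positive")
    sf$sf <- pmax(sf$sf, sf_floor)
  }
  sf |>
    dplyr::left_join(dplyr::select(design, "condition_id", "role"),
                     by = "condition_id") |>
    dplyr::select("condition_id", "role", "experiment", "sf") |>
    dplyr::arrange(.data$condition_id, .data$experiment)
}

#' Summarise percent viability across experiments
#'
#' Percent viability against control: `100 * mean(sf)` with standard error
#' `100 * sd(sf) / sqrt(n)` taken over independent experiments.
#'
#' @param sf_records Output of [survival_fraction()].
#' @return A tibble with `condition_id`, `n_experiments`, `mean_pct`,
#'   `se_pct` per condition.
#' @export
percent_viability <- function(sf_records) {
  n_exp <- dplyr::n_distinct(sf_records$experiment)
  if (n_exp < 2) {
    input_error("percent_viability needs at least 2 experiments")
  }
  sf_records |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::summarise(
      n_experiments = dplyr::n(),
      mean_pct = 100 * mean(.data$sf),
      se_pct = 100 * sd(.data$sf) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Fit a linear standard curve
#'
#' Ordinary least-squares fit of measured signal on known quantity, as used
#' to convert fluorescence to migrated/invaded cell numbers and optical
#' density to analyte concentrations.
#'
#' @param points Data frame of calibration points.
#' @param quantity,signal Column names (strings) for the known quantity and
#'   the measured signal; defaults `"quantity"` and `"signal"`.
#' @return A `standard_curve` object with components `slope`, `intercept`,
#'   `r_squared`, `range` (of quantities) and the underlying `lm` fit.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_standard_curve <- function(points, quantity = "quantity",
                               signal = "signal") {
  points <- as_tibble(points)
  if (!all(c(quantity, signal) %in% names(points))) {
    schema_error(paste0("standard-curve points need columns '", quantity,
                        "' and '", signal, "'"))
  }
  x <- points[[quantity]]
  y <- points[[signal]]
  if (dplyr::n_distinct(x) < 2) {
    input_error("standard curve needs >= 2 distinct quantities")
  }
  if (sd(y) == 0) {
    input_error("degenerate standard curve: signal does not vary")
  }
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope == 0) {
    input_error("degenerate standard curve: zero or undefined slope")
  }
  # exactly-linear standards are legitimate; silence the perfect-fit notice
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         range = range(x), points = tibble(quantity = x, signal = y),
         fit = fit),
    class = "standard_curve"
  )
}

#' Invert a standard curve from signal to quantity
#'
#' Inverse prediction `(signal - intercept) / slope`. Signals outside the
#' calibrated signal range are returned but flagged as extrapolated rather
#' than raising an error.
#'
#' @param curve A [fit_standard_curve()] object.
#' @param signal Numeric vector of measured signals.
#' @return A tibble with `signal`, `quantity` and logical `extrapolated`.
#' @export
invert_standard_curve <- function(curve, signal) {
  stopifnot(inherits(curve, "standard_curve"))
  q <- (signal - curve$intercept) / curve$slope
  tibble(signal = signal, quantity = q,
         extrapolated = q < curve$range[1] | q > curve$range[2])
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("Linear standard curve:", nrow(x$points), "points\n")
  cat(sprintf("  signal = %.6g + %.6g * quantity   (R^2 = %.4f)\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  coefs <- suppressWarnings(summary(x$fit)$coefficients)
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = coefs[, "Std. Error"])
}

#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(r.squared = x$r_squared, n = nrow(x$points),
         quantity.min = x$range[1], quantity.max = x$range[2])
}
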