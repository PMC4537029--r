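#' Kinetic enzyme activity from a two-timepoint colorimetric read
#'
#' Converts the product amount generated between two reads into an
#' activity: `activity = B / ((t2 - t1) * V)` in nmol/min/ml, i.e. mU/ml.
#' Used for AST and ALT assays where `B` is the pyruvate amount obtained
#' from the pyruvate standard curve.
#'
#' @param b_nmol Product amount between the reads, nmol (from the standard
#'   curve).
#' @param t1_min,t2_min Times of the first and second read, minutes;
#'   `t2_min > t1_min`.
#' @param volume_ml Original sample volume in the reaction well, ml.
#' @return Activity in mU/ml. Linear in `b_nmol`, inversely linear in the
#'   time interval and the volume.
#' @examples
#' enzyme_activity(100, t1_min = 10, t2_min = 60, volume_ml = 0.005)
#' @export
enzyme_activity <- function(b_nmol, t1_min, t2_min, volume_ml) {
  if (any(t2_min <= t1_min)) input_error("t2_min must be greater than t1_min")
  if (any(volume_ml <= 0)) input_error("volume_ml must be positive")
  if (any(b_nmol < 0)) input_error("b_nmol must be nonnegative")
  b_nmol / ((t2_min - t1_min) * volume_ml)
}

#' Creatinine concentration from a two-read standard curve
#'
#' Kinetic Jaffe-style assay: the optical density at 1 minute is subtracted
#' from the optical density at 30 minutes for both standards and samples;
#' standard delta-ODs are regressed on known concentration and sample
#' concentrations are read off the inverted regression line.
#'
#' @param od_1min,od_30min Sample optical densities at the early and late
#'   read; vectors of equal length.
#' @param standards Data frame with columns `concentration` (mg/dL),
#'   `od_1min`, `od_30min`; >= 2 distinct concentrations.
#' @return A tibble with `delta_od`, `concentration` (mg/dL) and
#'   `extrapolated` per sample.
#' @export
creatinine_concentration <- function(od_1min, od_30min, standards) {
  standards <- as_tibble(standards)
  need <- c("concentration", "od_1min", "od_30min")
  missing <- setdiff(need, names(standards))
  if (length(missing) > 0) {
    schema_error(paste0("standards missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  curve <- fit_standard_curve(
    tibble(quantity = standards$concentration,
           signal = standards$od_30min - standards$od_1min)
  )
  delta <- od_30min - od_1min
  out <- invert_standard_curve(curve, delta)
  tibble(delta_od = delta, concentration = out$quantity,
         extrapolated = out$extrapolated)
}

#' Urea nitrogen concentration from endpoint standards
#'
#' Endpoint colorimetric assay read once (450 nm): standard ODs are
#' regressed on known concentration and sample concentrations come from
#' the inverted line.
#'
#' @param od Sample optical densities.
#' @param standards Data frame with columns `concentration` (mg/dL) and
#'   `od`; >= 2 distinct concentrations.
#' @return A tibble with `od`, `concentration` (mg/dL), `extrapolated`.
#' @export
urea_concentration <- function(od, standards) {
  standards <- as_tibble(standards)
  missing <- setdiff(c("concentration", "od"), names(standards))
  if (length(missing) > 0) {
    schema_error(paste0("standards missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  curve <- fit_standard_curve(
    tibble(quantity = standards$concentration, signal = standards$od)
  )
  out <- invert_standard_curve(curve, od)
  tibble(od = od, concentration = out$quantity,
         extrapolated = out$extrapolated)
}

#' Reference ranges for the murine serum toxicity panel
#'
#' Normal ranges used to flag kidney (creatinine, urea nitrogen) and liver
#' (AST, ALT) panel values in nude mice. Endpoints are inclusive, the usual
#' clinical-range convention.
#'
#' @return A tibble with `analyte`, `normal_low`, `normal_high`, `units`.
#' @export
normal_ranges <- function() {
  tibble(
    analyte = c("creatinine", "urea_nitrogen", "AST", "ALT"),
    normal_low = c(0.1, 2, 37, 7),
    normal_high = c(2.1, 71, 329, 227),
    units = c("mg/dL", "mg/dL", "mU/ml", "mU/ml")
  )
}

#' Flag toxicity-panel values against normal ranges
#'
#' @param values Data frame with columns `analyte` and `value`; analytes
#'   must appear in `ranges`.
#' @param ranges Reference ranges, default [normal_ranges()].
#' @return `values` joined with its range, plus `in_range` (closed
#'   interval) and `flag` in `{"in range", "below range", "above range"}`.
#' @export
flag_ranges <- function(values, ranges = normal_ranges()) {
  values <- as_tibble(values)
  missing <- setdiff(c("analyte", "value"), names(values))
  if (length(missing) > 0) {
    schema_error(paste0("values missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(unique(values$analyte), ranges$analyte)
  if (length(unknown) > 0) {
    input_error(paste0("unrecognised analyte(s): ",
                       paste(unknown, collapse = ", ")))
  }
  values |>
    dplyr::left_join(ranges, by = "analyte") |>
    dplyr::mutate(
      in_range = .data$value >= .data$normal_low &
        .data$value <= .data$normal_high,
      flag = dplyr::case_when(
        .data$value < .data$normal_low ~ "below range",
        .data$value > .data$normal_high ~ "above range",
        .default = "in range"
      )
    )
}
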