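#' Experimental-arm roles recognised in a treatment design
#'
#' A design assigns each well condition one of these roles: `blank` (medium
#' only, defines background), `untreated_control` (cells only, defines 100%
#' viability), `light_only`, `mono_ps` (photosensitizer without light),
#' `mono_inhibitor`, `pdt` (photosensitizer + light) and `combination`
#' (PDT followed by an inhibitor).
#'
#' @return Character vector of valid role labels.
#' @export
design_roles <- function() {
  c("blank", "untreated_control", "light_only", "mono_ps",
    "mono_inhibitor", "pdt", "combination")
}

design_columns <- c("condition_id", "role", "ps_dose_uM", "light_dose_Jcm2",
                    "inhibitor", "inhibitor_dose_ugml")
measurement_columns <- c("condition_id", "experiment", "replicate", "signal")

schema_error <- function(msg, ...) {
  abort(msg, class = "dlsynergy_schema_error", ...)
}

input_error <- function(msg, ...) {
  abort(msg, class = "dlsynergy_input_error", ...)
}

#' Validate a treatment design table
#'
#' Checks the schema used throughout the package: one row per experimental
#' arm with columns `condition_id`, `role`, `ps_dose_uM`, `light_dose_Jcm2`,
#' `inhibitor`, `inhibitor_dose_ugml`. Roles must come from [design_roles()];
#' blanks must carry zero doses; combination arms must carry positive
#' photosensitizer, light and inhibitor doses; ids must be unique.
#'
#' @param design A data frame of experimental arms.
#' @return The validated design as a tibble (invisibly usable in pipes).
#' @export
validate_design <- function(design) {
  design <- as_tibble(design)
  missing <- setdiff(design_columns, names(design))
  if (length(missing) > 0) {
    schema_error(paste0("design is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  bad_role <- setdiff(unique(design$role), design_roles())
  if (length(bad_role) > 0) {
    schema_error(paste0("unknown role(s): ", paste(bad_role, collapse = ", ")))
  }
  dup <- design$condition_id[duplicated(design$condition_id)]
  if (length(dup) > 0) {
    schema_error(paste0("duplicate condition_id: ",
                        paste(unique(dup), collapse = ", ")))
  }
  for (col in c("ps_dose_uM", "light_dose_Jcm2", "inhibitor_dose_ugml")) {
    if (any(is.na(design[[col]]) | design[[col]] < 0)) {
      schema_error(paste0("column ", col, " must be nonnegative and non-missing"))
    }
  }
  blanks <- dplyr::filter(design, .data$role == "blank")
  if (any(blanks$ps_dose_uM != 0 | blanks$light_dose_Jcm2 != 0 |
            blanks$inhibitor_dose_ugml != 0)) {
    schema_error("blank conditions must have all doses equal to 0")
  }
  comb <- dplyr::filter(design, .data$role == "combination")
  if (any(comb$ps_dose_uM <= 0 | comb$light_dose_Jcm2 <= 0 |
            comb$inhibitor_dose_ugml <= 0)) {
    schema_error(paste0("combination conditions need positive photosensitizer, ",
                        "light and inhibitor doses"))
  }
  design
}

#' Read and validate a treatment design CSV
#'
#' @param path Path to a CSV file with the [validate_design()] schema.
#'   Unknown columns are preserved but ignored.
#' @return A validated design tibble.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) input_error(paste0("no such file: ", path))
  validate_design(readr::read_csv(path, show_col_types = FALSE))
}

#' Validate a well-level measurement table against a design
#'
#' Measurements are long format, one row per well: `condition_id`,
#' `experiment` (integer, 1-based), `replicate` (integer, 1-based) and
#' `signal` (nonnegative, e.g. relative luminescence units). Every
#' `condition_id` must resolve in the design and every experiment must
#' contain at least one untreated-control well.
#'
#' @param measurements A data frame of well signals.
#' @param design A validated design (see [validate_design()]).
#' @return The validated measurement tibble.
#' @export
validate_measurements <- function(measurements, design) {
  measurements <- as_tibble(measurements)
  design <- validate_design(design)
  missing <- setdiff(measurement_columns, names(measurements))
  if (length(missing) > 0) {
    schema_error(paste0("measurements missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  dangling <- setdiff(unique(measurements$condition_id), design$condition_id)
  if (length(dangling) > 0) {
    schema_error(paste0("measurement rows reference undeclared condition_id: ",
                        paste(dangling, collapse = ", ")))
  }
  if (any(is.na(measurements$signal) | measurements$signal < 0)) {
    schema_error("signals must be nonnegative and non-missing")
  }
  if (any(measurements$experiment < 1 | measurements$replicate < 1)) {
    schema_error("experiment and replicate indices must be >= 1")
  }
  control_ids <- design$condition_id[design$role == "untreated_control"]
  by_exp <- split(measurements$condition_id, measurements$experiment)
  no_ctrl <- names(by_exp)[!vapply(by_exp, function(ids)
    any(ids %in% control_ids), logical(1))]
  if (length(no_ctrl) > 0) {
    schema_error(paste0("experiment(s) without an untreated_control row: ",
                        paste(no_ctrl, collapse = ", ")))
  }
  measurements
}

#' Read and validate a measurement CSV
#'
#' @inheritParams validate_measurements
#' @param path Path to a CSV file with the [validate_measurements()] schema.
#' @return A validated measurement tibble.
#' @export
read_measurements <- function(path, design) {
  if (!file.exists(path)) input_error(paste0("no such file: ", path))
  validate_measurements(readr::read_csv(path, show_col_types = FALSE), design)
}

#' Write a result table to CSV
#'
#' Plain UTF-8 CSV with period decimal separators; the write/read round trip
#' is lossless for the package's table schemas.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_results <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(x)
}

#' Pair each combination arm with its two monotherapy arms
#'
#' Under Bliss independence the expected survival of a combination is the
#' product of the monotherapy survival fractions, so every combination arm
#' must be matched to the PDT arm with the same photosensitizer and light
#' dose and the inhibitor arm with the same inhibitor and dose. Doses are
#' matched exactly (designs are categorical).
#'
#' @param design A design table (validated internally).
#' @return A tibble with one row per matched combination:
#'   `combination_id`, `pdt_id`, `inhibitor_id`. Combinations lacking a
#'   unique match are dropped with a warning naming them; two candidate
#'   mono arms with identical doses raise an error.
#' @export
match_triples <- function(design) {
  design <- validate_design(design)
  combs <- dplyr::filter(design, .data$role == "combination")
  if (nrow(combs) == 0) {
    return(tibble(combination_id = character(), pdt_id = character(),
                  inhibitor_id = character()))
  }
  pdt <- dplyr::filter(design, .data$role == "pdt")
  inh <- dplyr::filter(design, .data$role == "mono_inhibitor")
  rows <- purrr::pmap(combs, function(condition_id, ps_dose_uM,
                                      light_dose_Jcm2, inhibitor,
                                      inhibitor_dose_ugml, ...) {
    p <- pdt$condition_id[pdt$ps_dose_uM == ps_dose_uM &
                            pdt$light_dose_Jcm2 == light_dose_Jcm2]
    i <- inh$condition_id[inh$inhibitor == inhibitor &
                            inh$inhibitor_dose_ugml == inhibitor_dose_ugml]
    if (length(p) > 1 || length(i) > 1) {
      schema_error(paste0("ambiguous monotherapy match for combination ",
                          condition_id))
    }
    if (length(p) == 0 || length(i) == 0) {
      return(tibble(combination_id = condition_id,
                    pdt_id = NA_character_, inhibitor_id = NA_character_))
    }
    tibble(combination_id = condition_id, pdt_id = p, inhibitor_id = i)
  })
  out <- dplyr::bind_rows(rows)
  unmatched <- out$combination_id[is.na(out$pdt_id) | is.na(out$inhibitor_id)]
  if (length(unmatched) > 0) {
    warn(paste0("combination arm(s) without matching monotherapy arms ",
                "dropped: ", paste(unmatched, collapse = ", ")))
  }
  dplyr::filter(out, !is.na(.data$pdt_id) & !is.na(.data$inhibitor_id))
}

#' Build a factorial PDT-by-inhibitor design
#'
#' Constructs the standard viability-plate layout for a PDT combination
#' study: blank and untreated-control wells, a light-only arm, drug-only
#' (`mono_ps`) arms, inhibitor-only arms, PDT arms, and one combination arm
#' for every photosensitizer-dose by inhibitor-dose pair.
#'
#' @param ps_doses Photosensitizer doses in uM (default `c(50, 100)`).
#' @param inhibitor_doses Inhibitor doses in ug/ml (default `c(50, 100)`).
#' @param inhibitors Character vector of inhibitor names
#'   (default `"nimotuzumab"`).
#' @param light_dose Light dose in J/cm^2 used by every irradiated arm
#'   (default 1).
#' @return A validated design tibble.
#' @examples
#' grid_design()
#' nrow(match_triples(grid_design(inhibitors = c("nimotuzumab", "cetuximab"))))
#' @export
grid_design <- function(ps_doses = c(50, 100), inhibitor_doses = c(50, 100),
                        inhibitors = "nimotuzumab", light_dose = 1) {
  base <- tibble(
    condition_id = c("blank", "control", "light_only",
                     paste0("ce6_", ps_doses),
                     paste0("pdt_", ps_doses)),
    role = c("blank", "untreated_control", "light_only",
             rep("mono_ps", length(ps_doses)),
             rep("pdt", length(ps_doses))),
    ps_dose_uM = c(0, 0, 0, ps_doses, ps_doses),
    light_dose_Jcm2 = c(0, 0, light_dose, rep(0, length(ps_doses)),
                        rep(light_dose, length(ps_doses))),
    inhibitor = NA_character_,
    inhibitor_dose_ugml = 0
  )
  monos <- tidyr::expand_grid(inhibitor = inhibitors, dose = inhibitor_doses)
  mono_tbl <- tibble(
    condition_id = paste0(substr(monos$inhibitor, 1, 4), "_", monos$dose),
    role = "mono_inhibitor",
    ps_dose_uM = 0, light_dose_Jcm2 = 0,
    inhibitor = monos$inhibitor, inhibitor_dose_ugml = monos$dose
  )
  grid <- tidyr::expand_grid(inhibitor = inhibitors, ps = ps_doses,
                             dose = inhibitor_doses)
  comb_tbl <- tibble(
    condition_id = paste0("pdt", grid$ps, "_", substr(grid$inhibitor, 1, 4),
                          grid$dose),
    role = "combination",
    ps_dose_uM = grid$ps, light_dose_Jcm2 = light_dose,
    inhibitor = grid$inhibitor, inhibitor_dose_ugml = grid$dose
  )
  validate_design(dplyr::bind_rows(base, mono_tbl, comb_tbl))
}
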