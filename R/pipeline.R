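#' Validated configuration for a full pipeline run
#'
#' @param out_dir Output directory for the run bundle.
#' @param seed Integer seed controlling every simulated stage.
#' @param alpha Significance level for synergy calls, in (0, 1).
#' @param sf_floor Optional positive floor for nonpositive survival
#'   fractions (see [survival_fraction()]).
#' @param df_override Optional degrees-of-freedom override for DL tests.
#' @param endpoint_day Day for the in-vivo DL analog; `NULL` picks the
#'   last day common to all groups.
#' @param viability_spec,tumor_spec Optional [viability_sim_spec()] /
#'   [tumor_sim_spec()]; defaults are built from `seed`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, alpha = 0.05, sf_floor = NULL,
                       df_override = NULL, endpoint_day = NULL,
                       viability_spec = NULL, tumor_spec = NULL) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    input_error("alpha must lie in (0, 1)")
  }
  if (!is.null(endpoint_day) && endpoint_day <= 0) {
    input_error("endpoint_day must be positive")
  }
  if (!is.null(sf_floor) && sf_floor <= 0) {
    input_error("sf_floor must be positive")
  }
  seed <- as.integer(seed)
  structure(
    list(out_dir = out_dir, seed = seed, alpha = alpha, sf_floor = sf_floor,
         df_override = df_override, endpoint_day = endpoint_day,
         viability_spec = viability_spec %||% viability_sim_spec(seed = seed),
         tumor_spec = tumor_spec %||% tumor_sim_spec(seed = seed + 1L)),
    class = "run_config"
  )
}

#' Run the full simulate-to-report pipeline
#'
#' Chains every stage on synthetic data with known ground truth:
#' viability simulation, background correction, survival fractions,
#' percent viability, the DL synergy report, tumor cohort simulation,
#' growth summary, in-vivo DL, Kaplan-Meier estimation and the toxicity
#' panel. All tables are written as CSV under `config$out_dir` together
#' with a `manifest.json` recording the configuration, seed and package
#' version; a rerun with the same config is numerically identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)

  sim <- simulate_viability_experiment(config$viability_spec)
  write_results(sim$design, out("design.csv"))
  write_results(sim$measurements, out("measurements.csv"))

  corrected <- background_correct(sim$measurements, sim$design)
  sf <- survival_fraction(corrected, sim$design, sf_floor = config$sf_floor)
  write_results(sf, out("survival_fractions.csv"))
  write_results(percent_viability(sf), out("percent_viability.csv"))

  synergy <- synergy_table(sf, sim$design, alpha = config$alpha,
                           df_override = config$df_override)
  write_results(synergy, out("synergy_report.csv"))

  cohort <- simulate_tumor_cohort(config$tumor_spec)
  write_results(cohort$tumors, out("tumor_measurements.csv"))
  write_results(cohort$survival, out("survival_records.csv"))
  growth <- growth_summary(cohort$tumors)
  write_results(growth, out("growth_summary.csv"))
  invivo <- invivo_dl(cohort$tumors, endpoint_day = config$endpoint_day,
                      alpha = config$alpha,
                      df_override = config$df_override)
  write_results(tidy(invivo), out("invivo_synergy.csv"))
  km <- km_estimate(cohort$survival,
                    horizon_days = config$tumor_spec$horizon_days)
  write_results(tidy(km), out("km_curve.csv"))
  write_results(glance(km), out("km_summary.csv"))

  tox <- simulate_toxicity_reads(seed = config$seed + 2L)
  creat <- creatinine_concentration(tox$creatinine_samples$od_1min,
                                    tox$creatinine_samples$od_30min,
                                    tox$creatinine_standards)
  urea <- urea_concentration(tox$urea_samples$od, tox$urea_standards)
  kin <- tox$kinetic_reads |>
    dplyr::mutate(value = enzyme_activity(.data$b_nmol, .data$t1_min,
                                          .data$t2_min, .data$volume_ml))
  panel <- dplyr::bind_rows(
    tibble(analyte = "creatinine", sample_id = tox$creatinine_samples$sample_id,
           value = creat$concentration),
    tibble(analyte = "urea_nitrogen", sample_id = tox$urea_samples$sample_id,
           value = urea$concentration),
    dplyr::select(kin, "analyte", "sample_id", "value")
  ) |>
    flag_ranges()
  write_results(panel, out("toxicity_panel.csv"))

  manifest <- list(
    package = "dlsynergy",
    version = as.character(utils::packageVersion("dlsynergy")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed, alpha = config$alpha,
    sf_floor = config$sf_floor, df_override = config$df_override,
    endpoint_day = invivo$label,
    outputs = list.files(config$out_dir, pattern = "\\.csv$")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(list(design = sim$design, sf = sf, synergy = synergy,
                 growth = growth, invivo = invivo, km = km, panel = panel))
}
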