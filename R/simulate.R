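#' Combination survival fraction implied by a true DL
#'
#' Inverts the DL definition: given the two monotherapy survival fractions
#' and a true difference-in-logarithms, the combination survival is
#' `sf_comb = sf_a * sf_b * 10^(-true_dl)`. `true_dl = 0` gives the Bliss
#' additive product; positive values suppress survival below it.
#'
#' @param sf_a,sf_b Monotherapy survival fractions in (0, 1].
#' @param true_dl True DL in log10 units (default 0, additive).
#' @return The combination survival fraction (positive).
#' @examples
#' simulate_combination_sf(0.25, 0.8)          # 0.20, the additive product
#' simulate_combination_sf(0.25, 0.8, 1.0)     # one log10 unit below it
#' @export
simulate_combination_sf <- function(sf_a, sf_b, true_dl = 0) {
  if (any(!is.finite(c(sf_a, sf_b))) || any(c(sf_a, sf_b) <= 0)) {
    input_error("monotherapy survival fractions must be positive and finite")
  }
  sf_a * sf_b * 10^(-true_dl)
}

default_viability_truth <- function(design) {
  # typical magnitudes for a chlorin e6-PDT + EGFR-inhibitor viability plate
  sf <- dplyr::case_when(
    design$role == "untreated_control" ~ 1,
    design$role == "light_only" ~ 0.75,
    design$role == "mono_ps" ~ 0.9,
    design$role == "mono_inhibitor" ~ 0.85,
    design$role == "pdt" & design$ps_dose_uM >= 100 ~ 0.22,
    design$role == "pdt" ~ 0.25,
    .default = NA_real_
  )
  setNames(sf, design$condition_id)[!is.na(sf) &
                                      design$role != "untreated_control"]
}

#' Specification for a simulated viability assay
#'
#' Defines the ground truth and noise model for plate-level simulation:
#' each non-control arm has a true survival fraction, each combination arm
#' a true DL (its SF is derived from the matched monotherapy truths via
#' [simulate_combination_sf()]). Noise is Gaussian on log10 SF, drawn once
#' per condition and experiment (the experiment, not the well, is the unit
#' of biological replication); optional additive read noise acts per well.
#'
#' @param design A design table, default [grid_design()].
#' @param true_sf Named vector of true survival fractions for non-control,
#'   non-combination arms; defaults to typical PDT-study magnitudes.
#' @param true_dl Named vector (or scalar, recycled) of true DLs for the
#'   combination arms, default 0.25.
#' @param n_experiments Number of independent experiments, default 3.
#' @param replicates Wells per condition per experiment, default 3
#'   (triplicate).
#' @param noise_sd_log SD of the Gaussian noise on log10 SF, default 0.05.
#' @param control_signal_mean,blank_signal_mean Mean raw signal (RLU) of
#'   untreated-control and medium-only wells.
#' @param read_noise_sd SD of additive per-well read noise (RLU), default 0.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return A validated `viability_sim_spec` list.
#' @export
viability_sim_spec <- function(design = grid_design(), true_sf = NULL,
                               true_dl = 0.25, n_experiments = 3,
                               replicates = 3, noise_sd_log = 0.05,
                               control_signal_mean = 1e6,
                               blank_signal_mean = 5e3,
                               read_noise_sd = 0, seed = 1L) {
  design <- validate_design(design)
  true_sf <- true_sf %||% default_viability_truth(design)
  comb_ids <- design$condition_id[design$role == "combination"]
  if (length(true_dl) == 1 && is.null(names(true_dl))) {
    true_dl <- setNames(rep(true_dl, length(comb_ids)), comb_ids)
  }
  need_sf <- design$condition_id[!design$role %in%
                                   c("blank", "untreated_control",
                                     "combination")]
  missing_sf <- setdiff(need_sf, names(true_sf))
  if (length(missing_sf) > 0) {
    input_error(paste0("true_sf missing for condition(s): ",
                       paste(missing_sf, collapse = ", ")))
  }
  if (any(true_sf <= 0 | true_sf > 1)) {
    input_error("true_sf values must lie in (0, 1]")
  }
  missing_dl <- setdiff(comb_ids, names(true_dl))
  if (length(missing_dl) > 0) {
    input_error(paste0("true_dl missing for combination(s): ",
                       paste(missing_dl, collapse = ", ")))
  }
  if (n_experiments < 2) input_error("n_experiments must be >= 2")
  if (replicates < 1) input_error("replicates must be >= 1")
  if (noise_sd_log < 0 || read_noise_sd < 0) {
    input_error("noise SDs must be nonnegative")
  }
  if (blank_signal_mean < 0 || control_signal_mean <= blank_signal_mean) {
    input_error("control_signal_mean must exceed blank_signal_mean >= 0")
  }
  structure(
    list(design = design, true_sf = true_sf, true_dl = true_dl,
         n_experiments = as.integer(n_experiments),
         replicates = as.integer(replicates), noise_sd_log = noise_sd_log,
         control_signal_mean = control_signal_mean,
         blank_signal_mean = blank_signal_mean,
         read_noise_sd = read_noise_sd, seed = as.integer(seed)),
    class = "viability_sim_spec"
  )
}

# true SF per condition, with combination SFs derived from matched mono arms
spec_true_sf_full <- function(spec) {
  design <- spec$design
  sf <- spec$true_sf
  sf[design$condition_id[design$role == "untreated_control"]] <- 1
  triples <- suppressWarnings(match_triples(design))
  for (k in seq_len(nrow(triples))) {
    sf[triples$combination_id[k]] <- simulate_combination_sf(
      sf[[triples$pdt_id[k]]], sf[[triples$inhibitor_id[k]]],
      spec$true_dl[[triples$combination_id[k]]]
    )
  }
  sf
}

#' Simulate a multi-experiment viability assay
#'
#' Generates raw well signals for every condition in the spec's design:
#' per experiment and condition a realized SF is drawn as
#' `true SF * 10^eps`, `eps ~ N(0, noise_sd_log)` (untreated controls keep
#' SF = 1); the well signal is
#' `blank + SF * (control - blank) + read noise`. Blank wells carry the
#' blank level plus read noise. Output uses the long schema consumed by
#' [validate_measurements()]; the run is deterministic under the spec seed.
#'
#' @param spec A [viability_sim_spec()].
#' @return A list with `design`, `measurements` and `truth` (a tibble of
#'   per-condition true SFs for round-trip checks).
#' @export
simulate_viability_experiment <- function(spec) {
  stopifnot(inherits(spec, "viability_sim_spec"))
  design <- spec$design
  sf_true <- spec_true_sf_full(spec)
  withr::with_seed(spec$seed, {
    grid <- tidyr::expand_grid(
      condition_id = design$condition_id,
      experiment = seq_len(spec$n_experiments)
    ) |>
      dplyr::left_join(dplyr::select(design, "condition_id", "role"),
                       by = "condition_id")
    eps <- stats::rnorm(nrow(grid), 0, spec$noise_sd_log)
    grid$sf_realized <- dplyr::case_when(
      grid$role == "blank" ~ NA_real_,
      grid$role == "untreated_control" ~ 1,
      .default = unname(sf_true[grid$condition_id]) * 10^eps
    )
    wells <- tidyr::expand_grid(grid,
                                replicate = seq_len(spec$replicates))
    level <- ifelse(
      wells$role == "blank", spec$blank_signal_mean,
      spec$blank_signal_mean + wells$sf_realized *
        (spec$control_signal_mean - spec$blank_signal_mean)
    )
    signal <- level + stats::rnorm(nrow(wells), 0, spec$read_noise_sd)
    measurements <- tibble(
      condition_id = wells$condition_id,
      experiment = as.integer(wells$experiment),
      replicate = as.integer(wells$replicate),
      signal = pmax(signal, 0)
    )
  })
  list(design = design,
       measurements = validate_measurements(measurements, design),
       truth = tibble(condition_id = names(sf_true),
                      true_sf = unname(sf_true)))
}

#' Monte-Carlo per-experiment DL replicates
#'
#' Draws per-experiment survival fractions through the same noise model as
#' the plate-level generator (one log10-scale Gaussian per arm and
#' experiment) and returns the per-experiment DL for each simulated
#' dataset, without materialising well tables. Used for type-I-error and
#' recovery studies of [dl_test()].
#'
#' @param n_sims Number of simulated datasets.
#' @param true_dl True DL (log10 units), default 0 (additive null).
#' @param sf_a,sf_b True monotherapy survival fractions.
#' @param noise_sd_log Per-arm SD of the log10 noise, default 0.05.
#' @param n_experiments Experiments per dataset, default 3.
#' @param seed Integer seed.
#' @return A matrix of DLs, `n_sims` rows by `n_experiments` columns.
#' @export
simulate_dl_replicates <- function(n_sims, true_dl = 0, sf_a = 0.25,
                                   sf_b = 0.8, noise_sd_log = 0.05,
                                   n_experiments = 3, seed = 1L) {
  sf_comb0 <- simulate_combination_sf(sf_a, sf_b, true_dl)
  withr::with_seed(as.integer(seed), {
    n <- n_sims * n_experiments
    sf_pdt <- sf_a * 10^stats::rnorm(n, 0, noise_sd_log)
    sf_mono <- sf_b * 10^stats::rnorm(n, 0, noise_sd_log)
    sf_comb <- sf_comb0 * 10^stats::rnorm(n, 0, noise_sd_log)
    matrix(dl_statistic(sf_pdt, sf_mono, sf_comb),
           nrow = n_sims, ncol = n_experiments)
  })
}

#' Specification for a simulated xenograft cohort
#'
#' Each group grows exponentially: an animal's volume at day `t` is
#' `initial_volume * exp(growth_rate * multiplier * jitter * t)` where the
#' per-animal `jitter` is lognormal with SD `rate_sd_log`. Treatment acts
#' as a multiplier on the log-growth rate, so the Bliss-additive null for
#' the combination is `m_comb = m_pdt + m_mono - 1` (volume ratios
#' multiply). Diameters are derived assuming a sphere, then jittered with
#' Gaussian caliper noise.
#'
#' @param groups Tibble with `group`, `n_animals`, `initial_volume_mm3`,
#'   `growth_rate` (per day, natural-log scale) and `multiplier`. The
#'   default emulates a 4-arm study: control (multiplier 1), two
#'   monotherapies (0.6 each) and a regressing combination (-0.3), 10
#'   animals each, 200 mm^3 enrolment volume, control rate 0.072/day
#'   (ceiling reached near day 32).
#' @param days Measurement days, default every 3 days to day 90.
#' @param diameter_noise_sd Caliper noise SD in mm, default 0.3.
#' @param rate_sd_log SD of the lognormal per-animal growth-rate jitter,
#'   default 0.15.
#' @param ceiling_mm3 Ethical volume limit, default 2000.
#' @param horizon_days Monitoring horizon, default 90.
#' @param seed Integer seed.
#' @return A validated `tumor_sim_spec` list.
#' @export
tumor_sim_spec <- function(groups = NULL, days = seq(0, 90, by = 3),
                           diameter_noise_sd = 0.3, rate_sd_log = 0.15,
                           ceiling_mm3 = 2000, horizon_days = 90,
                           seed = 1L) {
  groups <- groups %||% tibble(
    group = c("control", "pdt", "inhibitor", "combination"),
    n_animals = 10L,
    initial_volume_mm3 = 200,
    growth_rate = 0.072,
    multiplier = c(1, 0.6, 0.6, -0.3)
  )
  groups <- as_tibble(groups)
  need <- c("group", "n_animals", "initial_volume_mm3", "growth_rate",
            "multiplier")
  missing <- setdiff(need, names(groups))
  if (length(missing) > 0) {
    schema_error(paste0("groups missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (any(groups$initial_volume_mm3 >= ceiling_mm3)) {
    input_error("ceiling_mm3 must exceed every initial volume")
  }
  if (horizon_days <= 0) input_error("horizon_days must be positive")
  if (any(groups$n_animals < 1)) input_error("each group needs >= 1 animal")
  if (diameter_noise_sd < 0 || rate_sd_log < 0) {
    input_error("noise SDs must be nonnegative")
  }
  structure(
    list(groups = groups, days = sort(unique(days)),
         diameter_noise_sd = diameter_noise_sd, rate_sd_log = rate_sd_log,
         ceiling_mm3 = ceiling_mm3, horizon_days = horizon_days,
         seed = as.integer(seed)),
    class = "tumor_sim_spec"
  )
}

#' Simulate a xenograft tumor-growth cohort
#'
#' Generates per-animal diameter time series under the [tumor_sim_spec()]
#' growth model. An animal whose realized volume reaches the ceiling on a
#' measurement day gets an event that day and is no longer measured;
#' animals alive at the horizon are censored there. Deterministic under
#' the spec seed.
#'
#' @param spec A [tumor_sim_spec()].
#' @return A list with `tumors` (animal_id, group, day, d1_mm, d2_mm,
#'   d3_mm) and `survival` (animal_id, group, time_days, event).
#' @export
simulate_tumor_cohort <- function(spec) {
  stopifnot(inherits(spec, "tumor_sim_spec"))
  withr::with_seed(spec$seed, {
    animals <- spec$groups |>
      dplyr::rowwise() |>
      dplyr::group_map(function(g, ...) {
        tibble(
          animal_id = paste0(g$group, "_", seq_len(g$n_animals)),
          group = g$group,
          v0 = g$initial_volume_mm3,
          rate = g$growth_rate * g$multiplier *
            exp(stats::rnorm(g$n_animals, 0, spec$rate_sd_log))
        )
      }) |>
      dplyr::bind_rows()
    traj <- tidyr::expand_grid(animals, day = spec$days) |>
      dplyr::mutate(target_volume = .data$v0 * exp(.data$rate * .data$day))
    d_eq <- (6 * traj$target_volume / pi)^(1 / 3)
    noise <- matrix(stats::rnorm(3 * nrow(traj), 0, spec$diameter_noise_sd),
                    ncol = 3)
    traj$d1_mm <- pmax(d_eq + noise[, 1], 0.1)
    traj$d2_mm <- pmax(d_eq + noise[, 2], 0.1)
    traj$d3_mm <- pmax(d_eq + noise[, 3], 0.1)
    traj$volume_mm3 <- pi / 6 * traj$d1_mm * traj$d2_mm * traj$d3_mm
    per_animal <- traj |>
      dplyr::group_by(.data$animal_id, .data$group) |>
      dplyr::group_modify(function(d, key) {
        hit <- which(d$volume_mm3 >= spec$ceiling_mm3)
        if (length(hit) > 0) {
          keep <- d[seq_len(hit[1]), ]
          keep$event_time <- d$day[hit[1]]
          keep$event <- 1L
        } else {
          keep <- d
          keep$event_time <- spec$horizon_days
          keep$event <- 0L
        }
        keep
      }) |>
      dplyr::ungroup()
    tumors <- per_animal |>
      dplyr::select("animal_id", "group", "day", "d1_mm", "d2_mm", "d3_mm")
    surv <- per_animal |>
      dplyr::distinct(.data$animal_id, .data$group,
                      time_days = .data$event_time, .data$event)
  })
  list(tumors = tumors, survival = surv)
}

#' Simulate serum toxicity-panel reads with known truth
#'
#' Generates a creatinine two-read standard curve, urea endpoint
#' standards, AST/ALT kinetic reads and per-sample true values, with
#' additive Gaussian read noise on all optical densities, for exercising
#' the toxicity calculators end to end.
#'
#' @param n_samples Samples per analyte, default 4 (one per treatment arm).
#' @param true_creatinine,true_urea,true_ast,true_alt True values recycled
#'   over samples; defaults sit inside the murine normal ranges.
#' @param od_noise_sd Additive OD read noise SD, default 0.002.
#' @param seed Integer seed.
#' @return A list with `creatinine_standards`, `creatinine_samples`,
#'   `urea_standards`, `urea_samples`, `kinetic_reads` (AST/ALT, with
#'   pyruvate `b_nmol`, times, volume) and `truth`.
#' @export
simulate_toxicity_reads <- function(n_samples = 4, true_creatinine = 0.7,
                                    true_urea = 13, true_ast = 50,
                                    true_alt = 15, od_noise_sd = 0.002,
                                    seed = 1L) {
  # linear calibrations chosen to resemble kit leaflets: OD per unit analyte
  creat_slope <- 0.08   # delta-OD per mg/dL over 30 min
  urea_slope <- 0.015   # OD per mg/dL at 450 nm
  t1 <- 10; t2 <- 60; v <- 0.005
  withr::with_seed(as.integer(seed), {
    cr_conc <- c(0, 0.5, 1, 2, 4)
    cr_std <- tibble(
      concentration = cr_conc,
      od_1min = 0.05 + stats::rnorm(length(cr_conc), 0, od_noise_sd),
      od_30min = 0.05 + creat_slope * cr_conc +
        stats::rnorm(length(cr_conc), 0, od_noise_sd)
    )
    cr_true <- rep_len(true_creatinine, n_samples)
    cr_samp <- tibble(
      sample_id = paste0("s", seq_len(n_samples)),
      od_1min = 0.05 + stats::rnorm(n_samples, 0, od_noise_sd),
      od_30min = 0.05 + creat_slope * cr_true +
        stats::rnorm(n_samples, 0, od_noise_sd)
    )
    ur_conc <- c(0, 5, 10, 20, 40, 80)
    ur_std <- tibble(
      concentration = ur_conc,
      od = 0.04 + urea_slope * ur_conc +
        stats::rnorm(length(ur_conc), 0, od_noise_sd)
    )
    ur_true <- rep_len(true_urea, n_samples)
    ur_samp <- tibble(
      sample_id = paste0("s", seq_len(n_samples)),
      od = 0.04 + urea_slope * ur_true + stats::rnorm(n_samples, 0, od_noise_sd)
    )
    kin_true <- c(rep_len(true_ast, n_samples), rep_len(true_alt, n_samples))
    kinetic <- tibble(
      sample_id = rep(paste0("s", seq_len(n_samples)), 2),
      analyte = rep(c("AST", "ALT"), each = n_samples),
      b_nmol = kin_true * (t2 - t1) * v,
      t1_min = t1, t2_min = t2, volume_ml = v
    )
  })
  list(
    creatinine_standards = cr_std, creatinine_samples = cr_samp,
    urea_standards = ur_std, urea_samples = ur_samp,
    kinetic_reads = kinetic,
    truth = tibble(
      analyte = c("creatinine", "urea_nitrogen", "AST", "ALT"),
      true_value = c(true_creatinine, true_urea, true_ast, true_alt)
    )
  )
}
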