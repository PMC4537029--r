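test_that("simulate_combination_sf inverts the DL definition", {
  expect_equal(simulate_combination_sf(0.25, 0.8, 0), 0.20)
  expect_equal(simulate_combination_sf(0.25, 0.8, 1), 0.02)
  expect_equal(simulate_combination_sf(0.5, 0.5, -0.30103), 0.5,
               tolerance = 1e-5)
  expect_error(simulate_combination_sf(0, 0.5), class = "dlsynergy_input_error")
})

test_that("viability simulation is seed-deterministic and round-trips truth", {
  spec <- viability_sim_spec(seed = 9)
  a <- simulate_viability_experiment(spec)
  b <- simulate_viability_experiment(spec)
  expect_identical(a$measurements, b$measurements)

  other <- simulate_viability_experiment(viability_sim_spec(seed = 10))
  expect_false(identical(a$measurements$signal, other$measurements$signal))

  # noiseless recovery of every true SF through the viability stage
  spec0 <- viability_sim_spec(noise_sd_log = 0, seed = 1)
  sim0 <- simulate_viability_experiment(spec0)
  sf0 <- survival_fraction(background_correct(sim0$measurements, sim0$design),
                           sim0$design)
  joined <- dplyr::inner_join(sf0, sim0$truth, by = "condition_id")
  expect_equal(joined$sf, joined$true_sf, tolerance = 1e-9)

  # generator output parses cleanly through the file interface
  fd <- withr::local_tempfile(fileext = ".csv")
  fm <- withr::local_tempfile(fileext = ".csv")
  write_results(sim0$design, fd)
  write_results(sim0$measurements, fm)
  expect_no_warning(read_measurements(fm, read_design(fd)))
})

test_that("plate-level simulation is unbiased for the true DL", {
  true_dl <- 0.3
  dls <- vapply(1:120, function(i) {
    spec <- viability_sim_spec(
      design = grid_design(ps_doses = 50, inhibitor_doses = 50),
      true_dl = true_dl, noise_sd_log = 0.05, seed = 1000 + i)
    sim <- simulate_viability_experiment(spec)
    sf <- survival_fraction(
      background_correct(sim$measurements, sim$design), sim$design)
    mean(dl_replicates(sf, match_triples(sim$design))$dl)
  }, numeric(1))
  mc_se <- sd(dls) / sqrt(length(dls))
  expect_lt(abs(mean(dls) - true_dl), 3 * mc_se)
})

test_that("tumor cohort simulation respects ceiling, horizon and seed", {
  spec <- tumor_sim_spec(seed = 4)
  a <- simulate_tumor_cohort(spec)
  b <- simulate_tumor_cohort(spec)
  expect_identical(a, b)
  expect_true(all(a$survival$time_days <= spec$horizon_days))
  expect_true(all(a$survival$event %in% c(0L, 1L)))
  # measurements stop at the event day
  merged <- dplyr::left_join(a$tumors, a$survival,
                             by = c("animal_id", "group"))
  expect_true(all(merged$day <= merged$time_days))

  # zero growth keeps every animal below the ceiling: all censored
  flat <- tumor_sim_spec(
    groups = tibble::tibble(group = "control", n_animals = 5,
                            initial_volume_mm3 = 200, growth_rate = 0.07,
                            multiplier = 0),
    seed = 1)
  surv_flat <- simulate_tumor_cohort(flat)$survival
  expect_true(all(surv_flat$event == 0))
  expect_true(all(surv_flat$time_days == 90))

  # deterministic fast growth crosses the ceiling exactly when the
  # closed-form exponential does: 200*exp(0.15 t) >= 2000 at t >= 15.35,
  # first measurement day past that is 18
  fast <- tumor_sim_spec(
    groups = tibble::tibble(group = "control", n_animals = 4,
                            initial_volume_mm3 = 200, growth_rate = 0.15,
                            multiplier = 1),
    diameter_noise_sd = 0, rate_sd_log = 0, seed = 1)
  surv_fast <- simulate_tumor_cohort(fast)$survival
  expect_true(all(surv_fast$event == 1))
  expect_true(all(surv_fast$time_days == 18))
})

test_that("additive-by-construction cohorts yield an in-vivo DL near zero", {
  # multipliers on the log-growth rate: the Bliss null is
  # m_comb = m_pdt + m_mono - 1
  spec <- tumor_sim_spec(
    groups = tibble::tibble(
      group = c("control", "pdt", "inhibitor", "combination"),
      n_animals = 6, initial_volume_mm3 = 200, growth_rate = 0.05,
      multiplier = c(1, 0.6, 0.7, 0.3)),
    diameter_noise_sd = 0, rate_sd_log = 0, seed = 1)
  cohort <- simulate_tumor_cohort(spec)
  fit <- suppressWarnings(invivo_dl(cohort$tumors, endpoint_day = 30))
  expect_equal(fit$estimate, 0, tolerance = 1e-9)

  # with honest measurement noise the same null cohort is called additive:
  # the estimate stays near zero relative to its own confidence interval
  noisy <- simulate_tumor_cohort(tumor_sim_spec(
    groups = spec$groups, diameter_noise_sd = 0.3, rate_sd_log = 0.1,
    seed = 2))
  fit_n <- invivo_dl(noisy$tumors, endpoint_day = 30)
  expect_true(fit_n$conf.low < 0 & fit_n$conf.high > 0)
})

test_that("toxicity read simulation recovers its ground truth", {
  tox <- simulate_toxicity_reads(seed = 6, od_noise_sd = 0)
  creat <- creatinine_concentration(tox$creatinine_samples$od_1min,
                                    tox$creatinine_samples$od_30min,
                                    tox$creatinine_standards)
  expect_equal(creat$concentration, rep(0.7, 4), tolerance = 1e-9)
  urea <- urea_concentration(tox$urea_samples$od, tox$urea_standards)
  expect_equal(urea$concentration, rep(13, 4), tolerance = 1e-9)
  act <- enzyme_activity(tox$kinetic_reads$b_nmol, tox$kinetic_reads$t1_min,
                         tox$kinetic_reads$t2_min,
                         tox$kinetic_reads$volume_ml)
  expect_equal(act, rep(c(50, 15), each = 4))
})
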