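test_that("tumor volume follows the ellipsoid formula and its symmetries", {
  expect_equal(tumor_volume(1, 1, 1), pi / 6)
  expect_equal(tumor_volume(6, 6, 6), pi / 6 * 216)
  expect_equal(tumor_volume(2, 3, 4), tumor_volume(4, 3, 2))
  # homogeneous of degree 3
  expect_equal(tumor_volume(2 * 1.5, 3 * 1.5, 4 * 1.5),
               1.5^3 * tumor_volume(2, 3, 4))
  expect_error(tumor_volume(0, 1, 1), class = "dlsynergy_input_error")
})

test_that("growth summary matches the closed-form noiseless trajectory", {
  spec <- tumor_sim_spec(
    groups = tibble::tibble(group = c("control", "pdt"), n_animals = 3,
                            initial_volume_mm3 = 200, growth_rate = 0.05,
                            multiplier = c(1, 0.5)),
    days = seq(0, 30, by = 10), diameter_noise_sd = 0, rate_sd_log = 0,
    seed = 1)
  cohort <- simulate_tumor_cohort(spec)
  gs <- growth_summary(cohort$tumors)
  ctrl <- dplyr::filter(gs, group == "control")
  expect_equal(ctrl$mean_volume, 200 * exp(0.05 * ctrl$day),
               tolerance = 1e-9)
  expect_equal(ctrl$se_volume, rep(0, nrow(ctrl)))
  expect_equal(ctrl$n, rep(3L, nrow(ctrl)))

  # single animal: SE reported missing
  solo <- dplyr::filter(cohort$tumors, animal_id == "pdt_1")
  expect_true(all(is.na(growth_summary(solo)$se_volume)))

  # invariant to row order
  shuffled <- cohort$tumors[sample(nrow(cohort$tumors)), ]
  expect_equal(growth_summary(shuffled), gs)
})

test_that("invivo_dl reduces to dl_statistic for one animal per group", {
  days <- c(0, 10)
  one_each <- tibble::tibble(
    animal_id = rep(c("c1", "p1", "n1", "x1"), each = 2),
    group = rep(c("control", "pdt", "inhibitor", "combination"), each = 2),
    day = rep(days, 4),
    d1_mm = c(6, 10, 6, 8, 6, 8.5, 6, 7),
    d2_mm = c(6, 10, 6, 8, 6, 8.5, 6, 7),
    d3_mm = c(6, 10, 6, 8, 6, 8.5, 6, 7)
  )
  vols <- add_tumor_volume(one_each)
  at10 <- dplyr::filter(vols, day == 10)
  v <- setNames(at10$volume_mm3, at10$group)
  expected <- dl_statistic(v[["pdt"]] / v[["control"]],
                           v[["inhibitor"]] / v[["control"]],
                           v[["combination"]] / v[["control"]])
  # two combination animals are required for an SE, so duplicate the arm
  dup <- dplyr::bind_rows(one_each, dplyr::mutate(
    dplyr::filter(one_each, animal_id == "x1"), animal_id = "x2"))
  fit <- invivo_dl(dup, endpoint_day = 10)
  expect_equal(fit$estimate, expected, tolerance = 1e-12)

  # missing group at the endpoint is a named error
  err <- expect_error(
    invivo_dl(dplyr::filter(dup, group != "pdt" | day != 10),
              endpoint_day = 10),
    class = "dlsynergy_input_error")
  expect_match(conditionMessage(err), "pdt")
  expect_error(invivo_dl(dplyr::filter(dup, group == "control"),
                         endpoint_day = 10),
               class = "dlsynergy_input_error")
})

test_that("events_from_volumes applies the ceiling and horizon rules", {
  tum <- tibble::tibble(
    animal_id = rep(c("a", "b"), each = 3),
    group = "g", day = rep(c(0, 10, 20), 2),
    d1_mm = c(6, 10, 16, 6, 7, 8),
    d2_mm = c(6, 10, 16, 6, 7, 8),
    d3_mm = c(6, 10, 16, 6, 7, 8)
  )
  ev <- events_from_volumes(tum, ceiling_mm3 = 2000, horizon_days = 90)
  expect_equal(ev$time_days[ev$animal_id == "a"], 20)  # 16mm sphere > 2cm^3
  expect_equal(ev$event[ev$animal_id == "a"], 1L)
  expect_equal(ev$time_days[ev$animal_id == "b"], 90)
  expect_equal(ev$event[ev$animal_id == "b"], 0L)
})

test_that("Kaplan-Meier estimate matches the brute-force product limit", {
  withr::with_seed(13, {
    times <- sample(c(5, 10, 10, 15, 20, 25, 30, 30, 40, 60), 10)
    events <- rep(1L, 10)
  })
  rec <- tibble::tibble(animal_id = paste0("a", 1:10), group = "g",
                        time_days = times, event = events)
  km <- km_estimate(rec)
  oracle <- km_oracle(times, events)
  got <- dplyr::filter(tidy(km), n_event > 0)
  expect_equal(got$time, oracle$time)
  expect_equal(got$estimate, oracle$estimate, tolerance = 1e-12)

  # no censoring: product-limit equals the empirical survival function
  emp <- vapply(oracle$time, function(t) mean(times > t), numeric(1))
  expect_equal(oracle$estimate, emp, tolerance = 1e-12)

  # with censoring the oracle still agrees
  events2 <- c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 1L, 1L, 0L)
  rec2 <- dplyr::mutate(rec, event = events2)
  km2 <- km_estimate(rec2)
  oracle2 <- km_oracle(rec2$time_days, rec2$event)
  got2 <- dplyr::filter(tidy(km2), n_event > 0)
  expect_equal(got2$estimate, oracle2$estimate, tolerance = 1e-12)

  # ordering invariance
  km3 <- km_estimate(rec2[sample(nrow(rec2)), ])
  expect_equal(tidy(km3), tidy(km2))

  # all censored: survival stays at 1
  all_cens <- dplyr::mutate(rec, event = 0L, time_days = 90)
  expect_equal(glance(km_estimate(all_cens))$pct_survival_horizon, 100)

  expect_error(km_estimate(dplyr::mutate(rec, time_days = 0)),
               class = "dlsynergy_input_error")
})
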