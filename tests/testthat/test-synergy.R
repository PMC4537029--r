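test_that("dl_statistic matches the log-ratio definition and its identities", {
  expect_equal(dl_statistic(0.25, 0.8, 0.20), 0)
  expect_equal(dl_statistic(0.25, 0.8, 0.05), log10(0.20 / 0.05))
  expect_equal(dl_statistic(0.25, 0.8, 0.40), -log10(2))

  # additive point is exact for random SFs; halving sf_comb adds log10(2)
  withr::with_seed(5, {
    a <- runif(50, 0.01, 1)
    b <- runif(50, 0.01, 1)
  })
  expect_equal(dl_statistic(a, b, a * b), rep(0, 50), tolerance = 1e-12)
  expect_equal(dl_statistic(a, b, a * b / 2) - dl_statistic(a, b, a * b),
               rep(log10(2), 50), tolerance = 1e-12)

  expect_error(dl_statistic(0, 0.5, 0.2), class = "dlsynergy_input_error")
  expect_error(dl_statistic(0.5, 0.5, -1), class = "dlsynergy_input_error")
})

test_that("dl_test reproduces the t-test from replicates and from summaries", {
  dls <- c(0.21, 0.27, 0.24)
  fit <- dl_test(dls)
  ref <- t.test(dls, mu = 0)
  expect_equal(fit$statistic, unname(ref$statistic))
  expect_equal(fit$p.value, ref$p.value)
  expect_equal(fit$df, 2)
  expect_equal(c(fit$conf.low, fit$conf.high), as.numeric(ref$conf.int),
               tolerance = 1e-12)

  # summary interface: published-style row
  s <- dl_test(dl_mean = 0.4840, dl_se = 0.1290, df = 4)
  expect_equal(s$p.value, 2 * pt(-0.4840 / 0.1290, 4))
  expect_equal(s$call_label, "synergistic")

  # degenerate and null cases
  expect_warning(z <- dl_test(dl_mean = 0.3, dl_se = 0, df = 2), "degenerate")
  expect_equal(z$p.value, 0)
  null <- dl_test(dl_mean = 0, dl_se = 0, df = 2)
  expect_equal(null$p.value, 1)
  expect_equal(null$call_label, "additive")
  zero_mean <- dl_test(dl_mean = 0, dl_se = 0.1, df = 2)
  expect_equal(zero_mean$statistic, 0)
  expect_equal(zero_mean$p.value, 1)

  expect_error(dl_test(c(0.2)), class = "dlsynergy_input_error")
  expect_error(dl_test(dl_mean = 0.2), class = "dlsynergy_input_error")
})

test_that("classification gates on significance before the sign of DL", {
  expect_equal(classify_synergy(0.5, 0.01), "synergistic")
  expect_equal(classify_synergy(-0.5, 0.01), "antagonistic")
  expect_equal(classify_synergy(0.5, 0.2), "additive")
  expect_equal(classify_synergy(-0.5, 0.2), "additive")
  # ties at exactly p = alpha stay additive (strict inequality)
  expect_equal(classify_synergy(0.5, 0.05), "additive")
})

test_that("p-values are invariant to the logarithm base of DL", {
  withr::with_seed(8, {
    sf_pdt <- runif(3, 0.1, 0.5)
    sf_mono <- runif(3, 0.5, 1)
    sf_comb <- runif(3, 0.01, 0.3)
  })
  p10 <- dl_test(dl_statistic(sf_pdt, sf_mono, sf_comb, base = 10))$p.value
  pe <- dl_test(dl_statistic(sf_pdt, sf_mono, sf_comb,
                             base = exp(1)))$p.value
  expect_equal(p10, pe, tolerance = 1e-12)
})

test_that("dl_replicates pairs arms within experiments and handles gaps", {
  d <- tiny_design()
  m <- tiny_measurements(sfs = list(pdt_50 = c(0.25, 0.25, 0.25),
                                    nimo_50 = c(0.8, 0.8, 0.8),
                                    comb_50_50 = c(0.1, 0.1, 0.1)))
  sf <- survival_fraction(background_correct(m, d), d)
  triples <- match_triples(d)
  reps <- dl_replicates(sf, triples)
  expect_equal(reps$dl, rep(log10(0.2 / 0.1), 3))

  # an experiment missing the combination arm is dropped with a warning
  sf_gap <- dplyr::filter(sf, !(condition_id == "comb_50_50" &
                                  experiment == 3))
  expect_warning(reps_gap <- dl_replicates(sf_gap, triples), "dropped")
  expect_equal(nrow(reps_gap), 2)

  # a single complete experiment cannot yield a standard error
  sf_one <- dplyr::filter(sf, experiment == 1 | condition_id != "comb_50_50")
  expect_warning(
    expect_error(dl_replicates(sf_one, triples),
                 class = "dlsynergy_input_error"))
})

test_that("synergy_table recovers known truth from simulated plates", {
  spec <- viability_sim_spec(true_dl = 0.3, noise_sd_log = 0, seed = 2)
  sim <- simulate_viability_experiment(spec)
  sf <- survival_fraction(background_correct(sim$measurements, sim$design),
                          sim$design)
  # noiseless: every per-experiment DL equals the true value exactly
  reps <- dl_replicates(sf, match_triples(sim$design))
  expect_equal(reps$dl, rep(0.3, nrow(reps)), tolerance = 1e-9)

  # low noise: all four combinations called synergistic
  spec_n <- viability_sim_spec(true_dl = 0.3, noise_sd_log = 0.02, seed = 3)
  sim_n <- simulate_viability_experiment(spec_n)
  sf_n <- survival_fraction(
    background_correct(sim_n$measurements, sim_n$design), sim_n$design)
  tab <- synergy_table(sf_n, sim_n$design)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$call == "synergistic"))
  expect_true(all(tab$df == 2))

  # empty design -> empty report
  empty <- synergy_table(sf_n, dplyr::filter(sim_n$design,
                                             role != "combination"))
  expect_equal(nrow(empty), 0)
})
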