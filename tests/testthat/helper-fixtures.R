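# Small in-code fixtures shared across test files.

# minimal two-arm design plus the supporting blank/control rows
tiny_design <- function() {
  tibble::tibble(
    condition_id = c("blank", "control", "pdt_50", "nimo_50", "comb_50_50"),
    role = c("blank", "untreated_control", "pdt", "mono_inhibitor",
             "combination"),
    ps_dose_uM = c(0, 0, 50, 0, 50),
    light_dose_Jcm2 = c(0, 0, 1, 0, 1),
    inhibitor = c(NA, NA, NA, "nimotuzumab", "nimotuzumab"),
    inhibitor_dose_ugml = c(0, 0, 0, 50, 50)
  )
}

# measurements with known per-experiment SFs and a flat blank level
tiny_measurements <- function(sfs = list(pdt_50 = c(0.25, 0.25, 0.25),
                                         nimo_50 = c(0.8, 0.8, 0.8),
                                         comb_50_50 = c(0.2, 0.2, 0.2)),
                              control_level = 1000, blank_level = 50,
                              n_experiments = 3) {
  rows <- list(
    tibble::tibble(condition_id = "blank",
                   experiment = seq_len(n_experiments),
                   replicate = 1L, signal = blank_level),
    tibble::tibble(condition_id = "control",
                   experiment = seq_len(n_experiments),
                   replicate = 1L, signal = blank_level + control_level)
  )
  for (id in names(sfs)) {
    rows[[id]] <- tibble::tibble(
      condition_id = id, experiment = seq_len(n_experiments),
      replicate = 1L, signal = blank_level + sfs[[id]] * control_level
    )
  }
  dplyr::bind_rows(rows)
}

# brute-force product-limit estimator over explicit risk sets
km_oracle <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    at_risk <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  tibble::tibble(time = ts, estimate = surv)
}
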