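#' Difference-in-logarithms (DL) synergy statistic
#'
#' Under independent action (Bliss independence) the expected survival of a
#' combination is the product of the monotherapy survival fractions,
#' `SF_add = SF_pdt * SF_mono`. The DL statistic measures the departure of
#' the observed combination from that expectation on the log scale:
#'
#' `DL = log10(SF_pdt) + log10(SF_mono) - log10(SF_comb)`
#'
#' Positive DL means the combination killed more cells than predicted
#' (synergy), negative DL means antagonism and zero means additivity.
#'
#' @param sf_pdt,sf_mono,sf_comb Survival fractions in (0, 1]; vectors
#'   recycle in the usual way.
#' @param base Logarithm base, default 10. The classification and p-value
#'   downstream are invariant to the base; only the DL magnitude rescales.
#' @return Numeric vector of DL values (log10 units by default).
#' @examples
#' dl_statistic(0.25, 0.8, 0.20)  # additive: exactly 0
#' dl_statistic(0.25, 0.8, 0.05)  # synergy: > 0
#' @export
dl_statistic <- function(sf_pdt, sf_mono, sf_comb, base = 10) {
  sfs <- c(sf_pdt, sf_mono, sf_comb)
  if (any(!is.finite(sfs)) || any(sfs <= 0)) {
    input_error("survival fractions must be positive and finite")
  }
  log(sf_pdt, base) + log(sf_mono, base) - log(sf_comb, base)
}

#' Classify a combination from its DL estimate and p-value
#'
#' The significance gate comes first: only combinations whose DL differs
#' significantly from zero (`p < alpha`, strict) are called synergistic
#' (DL > 0) or antagonistic (DL < 0); everything else is additive.
#'
#' @param dl Numeric vector of DL estimates.
#' @param p Numeric vector of two-sided p-values.
#' @param alpha Significance level, default 0.05.
#' @return Character vector in `{"synergistic", "additive", "antagonistic"}`.
#' @export
classify_synergy <- function(dl, p, alpha = 0.05) {
  dplyr::case_when(
    p < alpha & dl > 0 ~ "synergistic",
    p < alpha & dl < 0 ~ "antagonistic",
    .default = "additive"
  )
}

#' Test a DL estimate against the additive null
#'
#' Two-sided one-sample Student t-test of the mean DL against zero. Either
#' supply the per-experiment DL replicates in `dls` (then
#' `se = sd/sqrt(n)` and `df = n - 1` unless overridden), or supply the
#' summary triplet (`dl_mean`, `dl_se`, `df`) directly -- the latter lets
#' published summary rows be re-tested as printed.
#'
#' @param dls Numeric vector of per-experiment DL replicates (>= 2), or
#'   `NULL` when using the summary interface.
#' @param dl_mean,dl_se Mean and standard error of DL (summary interface).
#' @param df Degrees of freedom; defaults to `length(dls) - 1`.
#' @param alpha Significance level for the classification, default 0.05.
#' @param label Optional label carried into [tidy()] output.
#' @return A `dl_test` object with elements `estimate`, `std.error`, `df`,
#'   `statistic`, `p.value`, `conf.low`/`conf.high` (95% CI), `call_label`
#'   (the synergy call), `alpha` and `n`. Supports [tidy()], [glance()],
#'   `print()`.
#' @examples
#' dl_test(dl_mean = 0.4840, dl_se = 0.1290, df = 4)   # in-vivo style row
#' dl_test(c(0.21, 0.25, 0.24))
#' @export
dl_test <- function(dls = NULL, dl_mean = NULL, dl_se = NULL, df = NULL,
                    alpha = 0.05, label = NULL) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    input_error("alpha must lie in (0, 1)")
  }
  if (!is.null(dls)) {
    dls <- dls[is.finite(dls)]
    n <- length(dls)
    if (n < 2) input_error("need >= 2 DL replicates to estimate a standard error")
    dl_mean <- mean(dls)
    dl_se <- sd(dls) / sqrt(n)
    df <- df %||% (n - 1L)
  } else {
    if (is.null(dl_mean) || is.null(dl_se) || is.null(df)) {
      input_error("summary interface needs dl_mean, dl_se and df")
    }
    if (dl_se < 0) input_error("dl_se must be nonnegative")
    n <- NA_integer_
  }
  if (df < 1) input_error("df must be >= 1")
  if (dl_se == 0) {
    if (dl_mean == 0) {
      t_stat <- 0
      p <- 1
    } else {
      warn("dl_se is 0 with nonzero dl_mean: degenerate test, p set to 0")
      t_stat <- sign(dl_mean) * Inf
      p <- 0
    }
  } else {
    t_stat <- dl_mean / dl_se
    p <- 2 * pt(-abs(t_stat), df)
  }
  crit <- qt(0.975, df)
  structure(
    list(estimate = dl_mean, std.error = dl_se, df = df,
         statistic = t_stat, p.value = p,
         conf.low = dl_mean - crit * dl_se,
         conf.high = dl_mean + crit * dl_se,
         call_label = classify_synergy(dl_mean, p, alpha),
         alpha = alpha, n = n, label = label),
    class = "dl_test"
  )
}

#' @export
print.dl_test <- function(x, ...) {
  cat("DL synergy test", if (!is.null(x$label)) paste0("[", x$label, "]"), "\n")
  cat(sprintf("  DL = %.4f (SE %.4f, df %g), t = %.3f, p = %.4g\n",
              x$estimate, x$std.error, x$df, x$statistic, x$p.value))
  cat(sprintf("  call: %s (alpha = %g)\n", x$call_label, x$alpha))
  invisible(x)
}

#' @method tidy dl_test
#' @export
tidy.dl_test <- function(x, ...) {
  tibble(label = x$label %||% NA_character_,
         estimate = x$estimate, std.error = x$std.error, df = x$df,
         statistic = x$statistic, p.value = x$p.value,
         conf.low = x$conf.low, conf.high = x$conf.high,
         call = x$call_label)
}

#' @method glance dl_test
#' @export
glance.dl_test <- function(x, ...) {
  tibble(n = x$n, df = x$df, p.value = x$p.value, call = x$call_label,
         alpha = x$alpha)
}

#' Per-experiment DL replicates for matched combination triples
#'
#' For each combination triple and each experiment in which all three arms
#' were measured, computes the DL from that experiment's survival fractions
#' only, preserving the pairing of arms within an experiment. Experiments
#' missing any arm of a triple are dropped with a warning; fewer than two
#' complete experiments is an error (no standard error is possible).
#'
#' @param sf_records Output of [survival_fraction()].
#' @param triples Output of [match_triples()].
#' @param base Logarithm base for the DL, default 10.
#' @return A tibble with `combination_id`, `experiment`, `dl`.
#' @export
dl_replicates <- function(sf_records, triples, base = 10) {
  sf_lookup <- dplyr::select(sf_records, "condition_id", "experiment", "sf")
  rows <- purrr::pmap(triples, function(combination_id, pdt_id,
                                        inhibitor_id, ...) {
    wide <- tibble(experiment = sort(unique(sf_lookup$experiment))) |>
      dplyr::left_join(
        setNames(sf_lookup, c("condition_id", "experiment", "sf_pdt")) |>
          dplyr::filter(.data$condition_id == pdt_id) |>
          dplyr::select(-"condition_id"),
        by = "experiment") |>
      dplyr::left_join(
        setNames(sf_lookup, c("condition_id", "experiment", "sf_mono")) |>
          dplyr::filter(.data$condition_id == inhibitor_id) |>
          dplyr::select(-"condition_id"),
        by = "experiment") |>
      dplyr::left_join(
        setNames(sf_lookup, c("condition_id", "experiment", "sf_comb")) |>
          dplyr::filter(.data$condition_id == combination_id) |>
          dplyr::select(-"condition_id"),
        by = "experiment")
    complete <- stats::complete.cases(wide)
    if (any(!complete)) {
      warn(paste0("combination ", combination_id, ": experiment(s) ",
                  paste(wide$experiment[!complete], collapse = ", "),
                  " missing an arm; dropped"))
    }
    wide <- wide[complete, ]
    if (nrow(wide) < 2) {
      input_error(paste0("combination ", combination_id, ": fewer than 2 ",
                         "complete experiments, no standard error possible"))
    }
    tibble(combination_id = combination_id, experiment = wide$experiment,
           dl = dl_statistic(wide$sf_pdt, wide$sf_mono, wide$sf_comb,
                             base = base))
  })
  dplyr::bind_rows(rows)
}

#' Batch synergy report over all matched combinations
#'
#' Runs [dl_replicates()] and [dl_test()] for every combination triple in
#' the design and assembles the standard report: one row per combination
#' with DL mean, SE, degrees of freedom, t, p and the synergy call.
#'
#' @param sf_records Output of [survival_fraction()].
#' @param design The design table (triples are matched internally).
#' @param alpha Significance level, default 0.05.
#' @param df_override Optional degrees of freedom forced on every test
#'   (replaces `n - 1`).
#' @return A tibble of class `synergy_tbl` with columns `combination_id`,
#'   `treatment` (human-readable label), `n_experiments`, `dl`, `se`, `df`,
#'   `statistic`, `p.value`, `call`. Supports [autoplot()].
#' @export
synergy_table <- function(sf_records, design, alpha = 0.05,
                          df_override = NULL) {
  design <- validate_design(design)
  triples <- match_triples(design)
  if (nrow(triples) == 0) {
    out <- tibble(combination_id = character(), treatment = character(),
                  n_experiments = integer(), dl = double(), se = double(),
                  df = double(), statistic = double(), p.value = double(),
                  call = character())
    class(out) <- c("synergy_tbl", class(out))
    return(out)
  }
  reps <- dl_replicates(sf_records, triples)
  labels <- design |>
    dplyr::mutate(treatment = sprintf("PDT (%g uM) + %s (%g ug/ml)",
                                      .data$ps_dose_uM, .data$inhibitor,
                                      .data$inhibitor_dose_ugml)) |>
    dplyr::select("condition_id", "treatment")
  out <- reps |>
    dplyr::group_by(.data$combination_id) |>
    dplyr::group_modify(function(d, key) {
      fit <- dl_test(d$dl, df = df_override, alpha = alpha)
      tibble(n_experiments = length(d$dl), dl = fit$estimate,
             se = fit$std.error, df = fit$df, statistic = fit$statistic,
             p.value = fit$p.value, call = fit$call_label)
    }) |>
    dplyr::ungroup() |>
    dplyr::left_join(labels, by = c(combination_id = "condition_id")) |>
    dplyr::relocate("treatment", .after = "combination_id")
  class(out) <- c("synergy_tbl", class(out))
  out
}

#' Published combination-synergy summary rows
#'
#' Transcribed summary statistics (mean DL, SE of DL, printed p-value and
#' call) for PDT + nimotuzumab and PDT + cetuximab combinations across four
#' cell lines plus one in-vivo xenograft row, from a published chlorin
#' e6-PDT oral-cancer combination study. Printed values below a reporting
#' threshold appear as the threshold (e.g. `p_printed = "< 0.0001"`); the
#' numeric `p` column holds `NA` for those rows.
#'
#' @return A tibble with columns `cell_line`, `treatment`, `dl`, `se`,
#'   `p_printed`, `p`, `call`.
#' @export
reported_synergy <- function() {
  path <- system.file("extdata", "reported_synergy_table.csv",
                      package = "dlsynergy", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::mutate(p = suppressWarnings(as.numeric(.data$p_printed)))
}
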