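#' Ellipsoid tumor volume from three orthogonal diameters
#'
#' `volume = pi/6 * d1 * d2 * d3`, the standard ellipsoid approximation for
#' caliper measurements in three orthogonal directions. Symmetric in its
#' arguments and homogeneous of degree 3.
#'
#' @param d1,d2,d3 Diameters in mm, all positive; vectors recycle.
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(1, 1, 1)  # pi/6
#' @export
tumor_volume <- function(d1, d2, d3) {
  if (any(!is.finite(c(d1, d2, d3))) || any(c(d1, d2, d3) <= 0)) {
    input_error("all diameters must be positive and finite")
  }
  pi / 6 * d1 * d2 * d3
}

#' Add the derived volume column to a tumor measurement table
#'
#' @param tumors Data frame with columns `animal_id`, `group`, `day`,
#'   `d1_mm`, `d2_mm`, `d3_mm`.
#' @return The same tibble with a `volume_mm3` column appended.
#' @export
add_tumor_volume <- function(tumors) {
  tumors <- as_tibble(tumors)
  need <- c("animal_id", "group", "day", "d1_mm", "d2_mm", "d3_mm")
  missing <- setdiff(need, names(tumors))
  if (length(missing) > 0) {
    schema_error(paste0("tumor table missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  dplyr::mutate(tumors,
                volume_mm3 = tumor_volume(.data$d1_mm, .data$d2_mm,
                                          .data$d3_mm))
}

#' Per-group tumor growth summary
#'
#' Mean volume and standard error across animals, per group and day.
#' Animals leave the summary once they stop being measured (e.g. after
#' reaching the ethical volume ceiling), so the per-cell `n` is reported.
#' SE is `NA` when only one animal contributes.
#'
#' @param tumors Tumor measurement table (volume derived internally).
#' @param days Optional vector of days to keep; default all observed days.
#' @return A tibble with `group`, `day`, `n`, `mean_volume`, `se_volume`.
#' @export
growth_summary <- function(tumors, days = NULL) {
  tumors <- add_tumor_volume(tumors)
  if (!is.null(days)) tumors <- dplyr::filter(tumors, .data$day %in% days)
  tumors |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_volume = mean(.data$volume_mm3),
      se_volume = ifelse(dplyr::n() > 1,
                         sd(.data$volume_mm3) / sqrt(dplyr::n()), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$group, .data$day)
}

#' In-vivo DL synergy analog on relative tumor burden
#'
#' Applies the difference-in-logarithms statistic to xenograft volumes: the
#' survival-fraction analog of an animal is its tumor volume at a fixed
#' endpoint day divided by the mean control volume on that day. Group-mean
#' SF analogs for the two monotherapy arms are combined with per-animal
#' combination SFs, giving one DL replicate per combination animal
#' (df = number of combination animals - 1 by default).
#'
#' @param tumors Tumor measurement table.
#' @param endpoint_day Day at which volumes are compared; default is the
#'   last day on which all four groups still have measurements.
#' @param roles Named character vector mapping the analysis roles
#'   `control`, `pdt`, `mono`, `combination` to group labels in the table.
#' @param alpha Significance level, default 0.05.
#' @param df_override Optional degrees of freedom override.
#' @return A `dl_test` object labelled with the endpoint day.
#' @export
invivo_dl <- function(tumors, endpoint_day = NULL,
                      roles = c(control = "control", pdt = "pdt",
                                mono = "inhibitor",
                                combination = "combination"),
                      alpha = 0.05, df_override = NULL) {
  need <- c("control", "pdt", "mono", "combination")
  if (!all(need %in% names(roles))) {
    input_error("roles must name control, pdt, mono and combination groups")
  }
  tumors <- add_tumor_volume(tumors)
  tumors <- dplyr::filter(tumors, .data$group %in% roles)
  if (is.null(endpoint_day)) {
    common <- tumors |>
      dplyr::distinct(.data$group, .data$day) |>
      dplyr::count(.data$day) |>
      dplyr::filter(.data$n == length(unique(roles)))
    if (nrow(common) == 0) input_error("no day common to all four groups")
    endpoint_day <- max(common$day)
  }
  at_end <- dplyr::filter(tumors, .data$day == endpoint_day)
  missing_groups <- setdiff(unname(roles), unique(at_end$group))
  if (length(missing_groups) > 0) {
    input_error(paste0("group(s) not measured at day ", endpoint_day, ": ",
                       paste(missing_groups, collapse = ", ")))
  }
  control_mean <- mean(at_end$volume_mm3[at_end$group == roles[["control"]]])
  sf_of <- function(g) at_end$volume_mm3[at_end$group == g] / control_mean
  sf_pdt <- mean(sf_of(roles[["pdt"]]))
  sf_mono <- mean(sf_of(roles[["mono"]]))
  sf_comb <- sf_of(roles[["combination"]])
  dls <- dl_statistic(sf_pdt, sf_mono, sf_comb)
  if (length(dls) == 1) {
    # single combination animal: point estimate only, no SE possible
    input_error("need >= 2 combination animals at the endpoint day")
  }
  dl_test(dls, df = df_override, alpha = alpha,
          label = paste0("in-vivo DL at day ", endpoint_day))
}

#' Derive ethical-limit survival records from tumor measurements
#'
#' An animal gets an event at the first measurement day on which its volume
#' reaches the ceiling; animals never reaching it are censored at the
#' horizon. No interpolation between measurement days is performed.
#'
#' @param tumors Tumor measurement table.
#' @param ceiling_mm3 Ethical volume limit in mm^3, default 2000 (2 cm^3).
#' @param horizon_days Monitoring horizon in days, default 90.
#' @return A tibble with `animal_id`, `group`, `time_days`, `event`.
#' @export
events_from_volumes <- function(tumors, ceiling_mm3 = 2000,
                                horizon_days = 90) {
  tumors <- add_tumor_volume(tumors)
  tumors |>
    dplyr::group_by(.data$animal_id, .data$group) |>
    dplyr::summarise(
      time_days = if (any(.data$volume_mm3 >= ceiling_mm3))
        min(.data$day[.data$volume_mm3 >= ceiling_mm3]) else horizon_days,
      event = as.integer(any(.data$volume_mm3 >= ceiling_mm3)),
      .groups = "drop"
    )
}

#' Kaplan-Meier survival estimate per treatment group
#'
#' Product-limit estimate of the survival function under right-censoring,
#' per group, with the usual convention that events precede censorings at
#' tied times. Computed via [survival::survfit()].
#'
#' @param records Data frame with `animal_id`, `group`, `time_days`,
#'   `event` (1 = reached ceiling/death, 0 = censored).
#' @param horizon_days Day at which percent survival is reported,
#'   default 90.
#' @return A `km_fit` object. [tidy()] returns the step function
#'   (`group`, `time`, `n_risk`, `n_event`, `n_censor`, `estimate`);
#'   [glance()] returns per-group `n`, `events`, `pct_survival_horizon`
#'   and `median_survival`; [autoplot()] draws the curves.
#' @export
km_estimate <- function(records, horizon_days = 90) {
  records <- as_tibble(records)
  need <- c("animal_id", "group", "time_days", "event")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    schema_error(paste0("survival table missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(records$time_days) | records$time_days <= 0)) {
    input_error("survival times must be positive")
  }
  fit <- survival::survfit(
    survival::Surv(time_days, event) ~ group, data = records
  )
  groups <- if (is.null(fit$strata)) unique(records$group) else
    sub("^group=", "", names(fit$strata))
  lens <- if (is.null(fit$strata)) length(fit$time) else as.vector(fit$strata)
  curve <- tibble(
    group = rep(groups, lens),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, estimate = fit$surv
  )
  structure(
    list(curve = curve, records = records, horizon_days = horizon_days,
         survfit = fit),
    class = "km_fit"
  )
}

km_survival_at <- function(curve_one_group, time) {
  drops <- curve_one_group[curve_one_group$time <= time, ]
  if (nrow(drops) == 0) 1 else drops$estimate[nrow(drops)]
}

#' @method tidy km_fit
#' @export
tidy.km_fit <- function(x, ...) x$curve

#' @method glance km_fit
#' @export
glance.km_fit <- function(x, ...) {
  x$records |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      cur <- x$curve[x$curve$group == key$group, ]
      med <- cur$time[cur$estimate <= 0.5]
      tibble(
        n = nrow(d), events = sum(d$event),
        pct_survival_horizon = 100 * km_survival_at(cur, x$horizon_days),
        median_survival = if (length(med) > 0) min(med) else NA_real_
      )
    }) |>
    dplyr::ungroup()
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier fit,", dplyr::n_distinct(x$records$group), "group(s),",
      nrow(x$records), "animals\n")
  print(glance(x))
  invisible(x)
}
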