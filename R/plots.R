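# ggplot2 methods for the main result types.

#' Plot NYHA-stratified incidence rates
#'
#' Point estimates with confidence intervals per event and NYHA class, on a
#' log scale (rates per 100 patient-years).
#'
#' @param object An `hcm_incidence` tibble from [estimate_incidence()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hcm_incidence
#' @export
autoplot.hcm_incidence <- function(object, ...) {
  dat <- mutate(object, class_lab = nyha_label(.data$nyha_class))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class_lab, y = .data$rate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$event), scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time-varying NYHA class",
                  y = "Events per 100 patient-years (95% CI)") +
    ggplot2::theme_minimal()
}

#' Plot a Kaplan-Meier / cumulative-risk curve
#'
#' @param object An `hcm_km` object from [km_time_to_first()].
#' @param type `"survival"` or `"risk"` (1 - survival).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hcm_km
#' @export
autoplot.hcm_km <- function(object, type = c("survival", "risk"), ...) {
  type <- match.arg(type)
  st <- tidy(object)
  st <- bind_rows(tibble(time = 0, n_risk = object$n, n_event = 0L,
                         n_censor = 0L, estimate = 1, risk = 0), st)
  y <- if (type == "survival") "estimate" else "risk"
  ggplot2::ggplot(st, ggplot2::aes(x = .data$time, y = .data[[y]])) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = if (type == "survival") "Survival" else
      "Cumulative risk") +
    ggplot2::theme_minimal()
}

#' Plot the NYHA class distribution report
#'
#' Grouped bars of per-class percentages at baseline and end of follow-up.
#'
#' @param report Output of [nyha_distribution_report()].
#' @return A ggplot object.
#' @export
plot_nyha_distribution <- function(report) {
  dat <- report |>
    filter(.data$measure %in% c("baseline", "end_of_followup"),
           .data$nyha_class %in% NYHA_LEVELS)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$nyha_class, y = .data$pct,
                                    fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "NYHA class", y = "Patients (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot stratified costs per patient-year
#'
#' Stacked per-component cost per patient-year by NYHA stratum.
#'
#' @param costs Output of [stratified_costs()].
#' @return A ggplot object.
#' @export
plot_cost_summary <- function(costs) {
  dat <- filter(costs, .data$component != "total")
  ggplot2::ggplot(dat, ggplot2::aes(
    x = factor(.data$stratum, levels = c(NYHA_LEVELS, "II+", "overall")),
    y = .data$cost_per_py, fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Time-varying NYHA stratum",
                  y = "Cost per patient-year (£)", fill = NULL) +
    ggplot2::theme_minimal()
}
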