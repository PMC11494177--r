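# ggplot2 views of the main result types.

#' Plot fitted exposure-response curves
#'
#' Evaluates each group's fitted response at constant lag vectors over a
#' temperature range and plots the relative risk against the cap temperature,
#' `f(T) / f(cap)`, averaged over the ensemble.
#'
#' @param fit An `exposure_fit`.
#' @param t_range Temperature range in degrees Celsius.
#' @param cap_c Reference temperature for the relative risk (default 20).
#' @return A ggplot object.
#' @export
plot_exposure_response <- function(fit, t_range = c(10, 32), cap_c = 20) {
  curves <- response_curve(fit, t_range, cap_c)
  ggplot(curves, aes(x = .data$tmean_c, y = .data$relative_risk,
                     colour = .data$sex)) +
    geom_line() +
    facet_wrap(~.data$age_band) +
    labs(x = "daily mean temperature [°C] (constant over the lag window)",
         y = sprintf("relative risk f(T) / f(%g)", cap_c),
         title = "Fitted exposure-response by sex and broad age") +
    theme_minimal()
}

#' Ensemble-mean relative-risk curve per sex x broad-age group
#'
#' @param fit An `exposure_fit`.
#' @param t_range Temperature range (degrees Celsius).
#' @param cap_c Reference temperature.
#' @param step Grid step in degrees Celsius.
#' @return Tibble `sex`, `age_band`, `tmean_c`, `relative_risk`.
#' @export
response_curve <- function(fit, t_range = c(10, 32), cap_c = 20, step = 0.5) {
  tt <- seq(t_range[1], t_range[2], by = step)
  lag_const <- matrix(rep(tt, each = 1), ncol = 1)[, rep(1, fit$config$l + 1)]
  lag_cap <- matrix(cap_c, nrow = 1, ncol = fit$config$l + 1)
  bind_rows(lapply(fit$groups, function(g) {
    rr <- rowMeans(vapply(fit$instances, function(inst) {
      response_factor(inst$response[[g]], lag_const) /
        response_factor(inst$response[[g]], lag_cap)
    }, numeric(length(tt))))
    parts <- strsplit(g, ":", fixed = TRUE)[[1]]
    tibble(sex = parts[1], age_band = parts[2], tmean_c = tt, relative_risk = rr)
  }))
}

#' @export
autoplot.projection_summary <- function(object, ...) {
  ggplot(object$summary, aes(x = .data$year)) +
    geom_ribbon(aes(ymin = .data$p10, ymax = .data$p90), alpha = 0.25) +
    geom_line(aes(y = .data$median)) +
    labs(x = NULL, y = "annual heat-related excess deaths",
         title = sprintf("Projected excess mortality ('%s')", object$scenario),
         subtitle = "median and 10th-90th percentile across ensemble members") +
    theme_minimal()
}

#' @export
autoplot.event_summary <- function(object, ...) {
  ggplot(object$daily, aes(x = .data$date, y = .data$excess)) +
    geom_col() +
    labs(x = NULL, y = "daily national excess deaths",
         title = sprintf("Heat event %s to %s: %.0f excess deaths (%.0f%% of the annual total)",
                         object$window[1], object$window[2], object$total,
                         object$share_pct)) +
    theme_minimal()
}
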