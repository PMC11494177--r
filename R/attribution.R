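# Heat attribution via the capped-temperature counterfactual: excess(s, t) =
# E(s, t | T) - E(s, t | min(T, cap)). The cap (default 20 C) is applied to
# the raw daily series before lag-matrix construction, so the whole lag
# window is capped; excess is computed per ensemble instance and averaged
# (equivalent to averaging first — the counterfactual difference is linear in
# the instance predictions).

#' Cap a temperature series
#'
#' Elementwise `min(tmean_c, cap_c)`; the no-heat counterfactual input.
#'
#' @param temps Tibble with a `tmean_c` column.
#' @param cap_c Cap in degrees Celsius (default 20).
#' @return `temps` with `tmean_c` capped.
#' @export
cap_series <- function(temps, cap_c = 20) {
  temps |> mutate(tmean_c = pmin(.data$tmean_c, cap_c))
}

#' Heat-related excess mortality via the capped counterfactual
#'
#' @param fit An [train_ensemble()] result.
#' @param temps Tibble `district_id`, `date`, `tmean_c`.
#' @param population Annual snapshots; defaults to the fit's.
#' @param cap_c Temperature cap in degrees Celsius (default 20).
#' @param level `"district_day"` (default) or `"national_day"`.
#' @param dow_correct Apply fitted day-of-week factors?
#' @param baseline_freeze_date Optional date pinning baseline rates (see
#'   [predict_expected_deaths()]).
#' @param clip_negative Clip negative daily excess at 0 for presentation
#'   (default `FALSE`: the estimator is reported unclipped).
#' @return Tibble with an `excess` column at the requested resolution.
#' @export
excess_mortality <- function(fit, temps, population = fit$population,
                             cap_c = 20,
                             level = c("district_day", "national_day"),
                             dow_correct = TRUE,
                             baseline_freeze_date = NULL,
                             clip_negative = FALSE) {
  level <- match.arg(level)
  orig <- predict_expected_deaths(fit, temps, population, level = level,
                                  dow_correct = dow_correct,
                                  baseline_freeze_date = baseline_freeze_date)
  capped <- predict_expected_deaths(fit, cap_series(temps, cap_c), population,
                                    level = level, dow_correct = dow_correct,
                                    baseline_freeze_date = baseline_freeze_date)
  out <- orig
  out$excess <- orig$expected - capped$expected
  if (clip_negative) out$excess <- pmax(out$excess, 0)
  out |> select(-"expected")
}

#' Count warm days per district and year
#'
#' @param district_temps Tibble `district_id`, `date`, `tmean_c`.
#' @param threshold Strict cutoff in degrees Celsius (default 20): a warm day
#'   has `tmean_c > threshold`.
#' @return Tibble `district_id`, `year`, `warm_days`.
#' @export
warm_day_count <- function(district_temps, threshold = 20) {
  district_temps |>
    mutate(year = as.integer(format(.data$date, "%Y"))) |>
    group_by(.data$district_id, .data$year) |>
    summarise(warm_days = sum(.data$tmean_c > threshold), .groups = "drop")
}

#' Summarise a heat event window
#'
#' Daily national excess over the window, per-district window totals with
#' per-million rates, the window total, and the window's share of the annual
#' total (the calendar year of the window's start).
#'
#' @param excess District-day excess tibble (`date`, `district_id`, `excess`),
#'   e.g. from [excess_mortality()]; must cover the window's calendar year.
#' @param population Annual snapshots for per-million rates (district weights
#'   from the snapshot year nearest the window start).
#' @param window Length-2 `Date` vector (inclusive).
#' @return List of class `event_summary`: `daily` (national daily excess in
#'   the window), `by_district` (window totals, population, `per_million`),
#'   `total`, `annual_total`, `share_pct`, `window`.
#' @export
event_summary <- function(excess, population, window) {
  window <- as.Date(window)
  assert_that(length(window) == 2 && window[1] <= window[2],
              "window must be two ordered dates")
  assert_that(min(excess$date) <= window[1] && max(excess$date) >= window[2],
              "window outside the excess series' date range")
  yr <- as.integer(format(window[1], "%Y"))
  in_win <- excess |> filter(.data$date >= window[1], .data$date <= window[2])
  annual <- excess |>
    filter(as.integer(format(.data$date, "%Y")) == yr) |>
    pull(.data$excess) |> sum()

  snap_year <- unique(population$year)[which.min(abs(unique(population$year) - yr))]
  pop_d <- population |>
    filter(.data$year == snap_year) |>
    group_by(.data$district_id) |>
    summarise(pop = sum(.data$pop), .groups = "drop")

  by_district <- in_win |>
    group_by(.data$district_id) |>
    summarise(excess = sum(.data$excess), .groups = "drop") |>
    left_join(pop_d, by = "district_id") |>
    mutate(per_million = if_else(.data$pop > 0, .data$excess / .data$pop * 1e6,
                                 NA_real_))
  if (any(by_district$pop <= 0 & abs(by_district$excess) > 0, na.rm = TRUE)) {
    warn("districts with zero population but nonzero excess: rate undefined")
  }

  total <- sum(in_win$excess)
  structure(
    list(
      daily = in_win |> group_by(.data$date) |>
        summarise(excess = sum(.data$excess), .groups = "drop"),
      by_district = by_district,
      total = total,
      annual_total = annual,
      share_pct = if (annual != 0) total / annual * 100 else NA_real_,
      window = window
    ),
    class = "event_summary"
  )
}

#' @export
print.event_summary <- function(x, ...) {
  cat(sprintf("<event_summary> %s to %s: %.0f excess deaths (%.1f%% of the %d total of %.0f)\n",
              x$window[1], x$window[2], x$total, x$share_pct,
              as.integer(format(x$window[1], "%Y")), x$annual_total))
  invisible(x)
}

#' Concentration of annual excess in the hottest days
#'
#' For one calendar year of daily national excess: the share of the annual
#' total carried by the `top_k` highest-excess days, and the fraction of
#' those days that are "disconnected" — with no other top-`k` day on an
#' adjacent calendar day.
#'
#' @param daily_excess Tibble `date`, `excess` covering one calendar year.
#' @param top_k Number of top days (default 10).
#' @return Tibble `year`, `top_k`, `top_share_pct`, `disconnected_frac`,
#'   `annual_total`. Years with zero annual excess yield `NA` shares.
#' @export
concentration_stats <- function(daily_excess, top_k = 10) {
  assert_that(top_k >= 1, "top_k must be >= 1")
  yrs <- unique(as.integer(format(daily_excess$date, "%Y")))
  assert_that(length(yrs) == 1, "daily_excess must cover a single calendar year")
  annual <- sum(daily_excess$excess)
  ord <- daily_excess |> arrange(dplyr::desc(.data$excess), .data$date)
  top <- ord$date[seq_len(min(top_k, nrow(ord)))]
  disconnected <- vapply(top, function(d) {
    !any(top %in% c(d - 1, d + 1))
  }, logical(1))
  tibble(
    year = yrs, top_k = length(top),
    top_share_pct = if (annual != 0) sum(ord$excess[seq_along(top)]) / annual * 100 else NA_real_,
    disconnected_frac = if (annual != 0) mean(disconnected) else NA_real_,
    annual_total = annual
  )
}
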