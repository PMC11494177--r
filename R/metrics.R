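#' Evaluate prediction quality against observed daily counts
#'
#' Computes RMSE and the coefficient of determination on all days and on the
#' warm-day subset (days whose national mean temperature exceeds the
#' threshold), together with the theoretical bounds implied by Poisson
#' observation noise for the predicted intensities: the RMSE of an ideal
#' predictor cannot fall below `sqrt(mean(lambda))`, and its R-squared cannot
#' exceed `1 - mean(lambda) / var(y)`.
#'
#' @param predicted Tibble `date`, `expected` (daily national predicted
#'   counts, e.g. `predict_expected_deaths(fit, temps, level = "national_day")`).
#' @param observed Tibble `date`, `deaths` at the same resolution.
#' @param national_temps Optional tibble `date`, `tmean_c` (e.g. from
#'   [national_mean_temperature()]) used for the warm-day filter; without it
#'   only the `"all"` subset is reported.
#' @param warm_threshold Warm-day cutoff in degrees Celsius (strict `>`,
#'   default 20).
#' @param exclude_years Calendar years excluded from metric evaluation.
#' @return Tibble with one row per subset (`all`, `warm`): `n`, `rmse`, `r2`,
#'   `rmse_lower_bound`, `r2_upper_bound`. Subsets with no days yield a row of
#'   `NA` metrics rather than an error.
#' @export
evaluate_metrics <- function(predicted, observed, national_temps = NULL,
                             warm_threshold = 20, exclude_years = integer(0)) {
  joined <- inner_join(predicted, observed, by = "date")
  assert_that(nrow(joined) > 0, "predicted and observed share no dates")
  joined <- joined |>
    filter(!(as.integer(format(.data$date, "%Y")) %in% exclude_years))
  if (!is.null(national_temps)) {
    joined <- joined |> left_join(national_temps, by = "date")
  }

  metric_row <- function(df, label) {
    if (nrow(df) == 0) {
      return(tibble(subset = label, n = 0L, rmse = NA_real_, r2 = NA_real_,
                    rmse_lower_bound = NA_real_, r2_upper_bound = NA_real_))
    }
    resid <- df$deaths - df$expected
    vy <- if (nrow(df) > 1) var(df$deaths) else NA_real_
    tibble(
      subset = label, n = nrow(df),
      rmse = sqrt(mean(resid^2)),
      r2 = if (!is.na(vy) && vy > 0) 1 - mean(resid^2) / vy else NA_real_,
      rmse_lower_bound = sqrt(mean(df$expected)),
      r2_upper_bound = if (!is.na(vy) && vy > 0) 1 - mean(df$expected) / vy else NA_real_
    )
  }

  out <- metric_row(joined, "all")
  if (!is.null(national_temps)) {
    out <- bind_rows(out,
                     metric_row(joined |> filter(.data$tmean_c > warm_threshold),
                                "warm"))
  }
  out
}
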