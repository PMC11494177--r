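#' Ground-truth baseline mortality specification
#'
#' Per-stratum daily baseline death rates for the synthetic generator:
#' log-linear in time (no seasonality), spatially uniform. Age dependence
#' follows a Gompertz-type curve on the 5-year band midpoints with a
#' multiplicative sex contrast.
#'
#' @param gompertz_a,gompertz_b Intercept and slope of the log annual rate
#'   against age in years: `annual rate = exp(a + b * age_mid)`, capped at 0.5.
#' @param male_ratio Male/female rate ratio (applied as `sqrt` up/down).
#' @param trend_per_year Linear trend of the log daily rate per year (shared by
#'   all strata), e.g. slow mortality improvement when negative.
#' @return Tibble `sex`, `age_band`, `log_daily_rate0` (log rate per
#'   person-day at the simulation's first day), `trend_per_year`.
#' @export
baseline_spec <- function(gompertz_a = -9.9, gompertz_b = 0.092,
                          male_ratio = 1.5, trend_per_year = -0.005) {
  bands <- age_bands_5yr()
  annual <- pmin(exp(gompertz_a + gompertz_b * band_midpoint(bands)), 0.5)
  daily <- annual / 365.25
  tibble(
    sex = rep(c("f", "m"), each = length(bands)),
    age_band = rep(bands, 2),
    log_daily_rate0 = c(log(daily / sqrt(male_ratio)), log(daily * sqrt(male_ratio))),
    trend_per_year = trend_per_year
  )
}

#' Simulate mortality with known temperature-dependent risk
#'
#' Expected deaths per (day, district, sex, 5-year age band) are
#' `baseline(t) * population(t) * f_true(lagged T) * dow(weekday)`; realised
#' deaths are independent Poisson draws. The ground-truth heat-related excess
#' is the difference between expected deaths under the original and under the
#' capped (`min(T, cap_c)`) temperature series, lag window included.
#'
#' @param region A [generate_region()] result.
#' @param district_temps Tibble `district_id`, `date`, `tmean_c` (daily,
#'   contiguous), e.g. `generate_temperature_fields(region)$district_temps`.
#' @param truth A [true_risk_model()].
#' @param baseline A [baseline_spec()] tibble; rates must be positive.
#' @param cap_c Temperature cap (degrees Celsius) defining the no-heat
#'   counterfactual for `excess_true` (default 20).
#' @return An object of class `synthetic_truth`: a list with
#'   `deaths` (tibble `date`, `district_id`, `sex`, `age_band`, `expected`,
#'   `deaths`, `excess_true`), plus `district_temps`, `truth`, `baseline`,
#'   `region`, and `cap_c`.
#' @examples
#' region <- generate_region(region_config(n_districts = 2, n_states = 1,
#'                                         years = 2020, n_stations = 3))
#' wx <- generate_temperature_fields(region)
#' truth <- generate_mortality_counts(region, wx$district_temps,
#'                                    true_risk_model(), baseline_spec())
#' sum(truth$deaths$deaths)
#' @export
generate_mortality_counts <- function(region, district_temps,
                                      truth = true_risk_model(),
                                      baseline = baseline_spec(),
                                      cap_c = 20) {
  assert_that(inherits(truth, "true_risk_model"), "truth must be a true_risk_model")
  assert_that(all(is.finite(baseline$log_daily_rate0)),
              "baseline rates must be positive and finite")
  l <- length(truth$lag_weights) - 1
  tm <- series_matrix(district_temps, "district_id")
  dates <- attr(tm, "dates")
  district_ids <- rownames(tm)
  nd <- nrow(tm); nt <- ncol(tm)

  f_orig <- risk_factor(truth, lag_matrix_from_mat(tm, l))
  f_cap <- risk_factor(truth, lag_matrix_from_mat(pmin_mat(tm, cap_c), l))
  Fo <- matrix(f_orig, nrow = nd) # district x day
  Fc <- matrix(f_cap, nrow = nd)

  dow <- truth$dow_factors[weekday_index(dates)]
  yrs <- as.numeric(dates - dates[1]) / 365.25
  st <- stratum_table()
  bkey <- paste(baseline$sex, baseline$age_band, sep = ":")
  assert_that(all(st$stratum %in% bkey), "baseline must cover all sex x age strata")
  b0 <- baseline$log_daily_rate0[match(st$stratum, bkey)]
  btr <- baseline$trend_per_year[match(st$stratum, bkey)]
  B <- exp(outer(b0, rep(1, nt)) + outer(btr, yrs)) # stratum x day

  P <- pop_array(region$population, dates, district_ids) # stratum x district x day

  ns <- nrow(st)
  # expected[s, r, t] = B[s,t] * P[s,r,t] * F[r,t] * dow[t]
  Bd <- B * rep(dow, each = ns) # stratum x day incl. dow
  expected <- array(0, dim = dim(P))
  excess <- array(0, dim = dim(P))
  for (r in seq_len(nd)) {
    expected[, r, ] <- (P[, r, ] * Bd) * rep(Fo[r, ], each = ns)
    excess[, r, ] <- (P[, r, ] * Bd) * rep(Fo[r, ] - Fc[r, ], each = ns)
  }

  realized <- with_seed(child_seed(region$config$seed, 3), {
    rpois(length(expected), lambda = as.vector(expected))
  })

  deaths <- tibble(
    date = rep(dates, each = ns * nd),
    district_id = rep(rep(district_ids, each = ns), times = nt),
    sex = rep(st$sex, times = nd * nt),
    age_band = rep(st$age_band, times = nd * nt),
    expected = as.vector(expected),
    deaths = realized,
    excess_true = as.vector(excess)
  )

  structure(
    list(deaths = deaths, district_temps = district_temps, truth = truth,
         baseline = baseline, region = region, cap_c = cap_c),
    class = "synthetic_truth"
  )
}

pmin_mat <- function(m, cap) {
  out <- pmin(m, cap)
  attributes(out) <- attributes(m)
  out
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d districts x %d days: %d deaths (%.0f expected), true excess %.1f\n",
              length(unique(x$deaths$district_id)),
              length(unique(x$deaths$date)),
              sum(x$deaths$deaths), sum(x$deaths$expected),
              sum(x$deaths$excess_true)))
  invisible(x)
}
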