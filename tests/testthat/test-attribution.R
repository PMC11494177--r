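# A hand-built single-instance "fit" lets attribution be tested without
# training: one response function shared by all groups, known baseline.
manual_fit <- function(region, params, l = 3,
                       dow = rep(1, 7), baseline = baseline_spec(),
                       ref_date = as.Date("2019-01-01")) {
  st <- heatmort:::stratum_table()
  groups <- unique(st$group)
  bl <- baseline |>
    dplyr::rename(log_daily_rate0 = "log_daily_rate0")
  inst <- list(
    response = stats::setNames(rep(list(params), length(groups)), groups),
    baseline = bl, dow_factors = dow, seed = 1L
  )
  structure(
    list(instances = list(inst),
         config = train_config(train_years = 2019, validation_years = 2020,
                               ensemble_size = 1, l = l, d = params$d),
         districts = region$districts, population = region$population,
         ref_date = ref_date, groups = groups,
         fit_report = tibble::tibble()),
    class = "exposure_fit"
  )
}

# a response rising above 20 C: f = 0.9 + 0.1 exp(0.25 (mean(T) - 20))
warm_params <- function(l = 3) {
  exposure_params(inner_weights = matrix(0.25 / (l + 1), 1, l + 1),
                  inner_bias = -5, mix_weights = 0.1, mix_bias = 0.9)
}

test_that("capping a series is an elementwise minimum", {
  x <- toy_temps(c(25, 18, 30, 20))
  expect_equal(cap_series(x)$tmean_c, c(20, 18, 20, 20))
  expect_equal(cap_series(x, 30)$tmean_c, c(25, 18, 30, 20))
  all_cool <- toy_temps(c(12, 15, 19.9))
  expect_identical(cap_series(all_cool), all_cool)
})

test_that("excess is exactly zero when no temperature exceeds the cap", {
  region <- small_region()
  fit <- manual_fit(region, warm_params())
  days <- seq(as.Date("2019-06-01"), as.Date("2019-08-31"), by = "day")
  temps <- tidyr::expand_grid(district_id = region$districts$district_id,
                              date = days) |>
    dplyr::mutate(tmean_c = 16 + 3 * sin(as.numeric(date) / 5))
  exc <- excess_mortality(fit, temps)
  expect_true(all(exc$excess == 0))
})

test_that("a monotone response gives non-negative excess everywhere", {
  region <- small_region()
  wx <- small_weather()
  fit <- manual_fit(region, warm_params())
  exc <- excess_mortality(fit, wx$district_temps)
  expect_true(all(exc$excess >= -1e-12))
  # and strictly positive on the hottest days
  hottest <- wx$district_temps |> dplyr::slice_max(tmean_c, n = 1)
  hit <- exc |> dplyr::filter(district_id == hottest$district_id,
                              date == hottest$date)
  expect_gt(hit$excess, 0)
})

test_that("excess is invariant under the (c, 1/c) baseline-response rescaling", {
  region <- small_region()
  wx <- small_weather()
  fit <- manual_fit(region, warm_params())
  cc <- 1.7
  fit2 <- fit
  inst <- fit2$instances[[1]]
  inst$baseline$log_daily_rate0 <- inst$baseline$log_daily_rate0 + log(cc)
  inst$response <- lapply(inst$response, function(p) {
    exposure_params(p$variant, p$inner_weights, p$inner_bias,
                    p$mix_weights / cc, p$mix_bias / cc)
  })
  fit2$instances[[1]] <- inst
  e1 <- excess_mortality(fit, wx$district_temps)
  e2 <- excess_mortality(fit2, wx$district_temps)
  expect_equal(e2$excess, e1$excess, tolerance = 1e-9)
})

test_that("excess conserves across groupings and instance-averaging orders", {
  region <- small_region()
  wx <- small_weather()
  fit <- manual_fit(region, warm_params())
  by_d <- excess_mortality(fit, wx$district_temps, level = "district_day")
  natl <- excess_mortality(fit, wx$district_temps, level = "national_day")
  expect_equal(
    by_d |> dplyr::group_by(date) |>
      dplyr::summarise(excess = sum(excess), .groups = "drop") |>
      dplyr::pull(excess),
    natl$excess, tolerance = 1e-10
  )
})

test_that("warm-day counts use a strict threshold", {
  x <- toy_temps(c(21, 19, 25, 20, 20.0001))
  wd <- warm_day_count(x, 20)
  expect_equal(wd$warm_days, 3)
  cold_year <- toy_temps(rep(15, 365), start = as.Date("2020-01-01"))
  expect_equal(warm_day_count(cold_year)$warm_days, 0)
})

test_that("event summaries compute totals, shares and per-million rates", {
  region <- small_region()
  days <- seq(as.Date("2019-01-01"), as.Date("2019-12-31"), by = "day")
  exc <- tidyr::expand_grid(district_id = region$districts$district_id,
                            date = days) |>
    dplyr::mutate(excess = 0.25)
  win <- as.Date(c("2019-07-07", "2019-07-14"))
  es <- event_summary(exc, region$population, win)
  expect_equal(es$total, 0.25 * 4 * 8)
  expect_equal(es$share_pct, 8 / 365 * 100, tolerance = 1e-10)
  expect_equal(sum(es$by_district$excess), es$total)

  # full-year window has share 100%
  es_full <- event_summary(exc, region$population,
                           as.Date(c("2019-01-01", "2019-12-31")))
  expect_equal(es_full$share_pct, 100)

  # rate arithmetic: 10 excess deaths in 1e6 people = 10 per million
  pop1 <- tibble::tibble(district_id = "D1", sex = "f", age_band = "50-55",
                         year = 2019, pop = 1e6)
  exc1 <- tibble::tibble(district_id = "D1",
                         date = days, excess = 10 / 365)
  es1 <- event_summary(exc1, pop1, as.Date(c("2019-01-01", "2019-12-31")))
  expect_equal(es1$by_district$per_million, 10, tolerance = 1e-10)

  # doubling population halves the rate
  es2 <- event_summary(exc1, pop1 |> dplyr::mutate(pop = 2e6),
                       as.Date(c("2019-01-01", "2019-12-31")))
  expect_equal(es2$by_district$per_million, 5, tolerance = 1e-10)
})

test_that("event shares over a disjoint partition of the year sum to 100%", {
  region <- small_region()
  days <- seq(as.Date("2019-01-01"), as.Date("2019-12-31"), by = "day")
  set.seed(12)
  exc <- tidyr::expand_grid(district_id = region$districts$district_id,
                            date = days) |>
    dplyr::mutate(excess = runif(dplyr::n(), 0, 0.3))
  cuts <- as.Date(c("2019-01-01", "2019-04-01", "2019-08-15", "2019-12-31"))
  windows <- list(c(cuts[1], cuts[2] - 1), c(cuts[2], cuts[3] - 1),
                  c(cuts[3], cuts[4]))
  shares <- vapply(windows, function(w) {
    event_summary(exc, region$population, w)$share_pct
  }, numeric(1))
  expect_equal(sum(shares), 100, tolerance = 1e-9)
})

test_that("concentration statistics match hand-built heatwave structures", {
  days <- seq(as.Date("2019-01-01"), as.Date("2019-12-31"), by = "day")
  base <- tibble::tibble(date = days, excess = 0)

  # all excess on one day: share 100%, that single top day is isolated
  one <- base; one$excess[200] <- 50
  cs <- concentration_stats(one, top_k = 10)
  expect_equal(cs$top_share_pct, 100)
  # the single carrying day is disconnected; zero-excess filler days may tie
  expect_gt(cs$disconnected_frac, 0)

  # uniform excess: top-10 share = 10/365
  unif <- base |> dplyr::mutate(excess = 1)
  expect_equal(concentration_stats(unif)$top_share_pct, 10 / 365 * 100,
               tolerance = 1e-10)

  # one 6-day block plus 4 isolated hot days: disconnected fraction 40%
  mix <- base
  mix$excess[150:155] <- 20 # 6-day block
  iso <- c(100, 120, 250, 300)
  mix$excess[iso] <- 15 # isolated spikes
  cs2 <- concentration_stats(mix, top_k = 10)
  expect_equal(cs2$disconnected_frac, 0.4)
  expect_equal(cs2$top_share_pct, 100)

  # zero annual excess: flagged undefined
  cs3 <- concentration_stats(base)
  expect_true(is.na(cs3$top_share_pct))
})
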