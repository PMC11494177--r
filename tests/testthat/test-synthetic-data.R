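test_that("degenerate single-state single-district region holds all population", {
  cfg <- region_config(n_states = 1, n_districts = 1, n_stations = 2,
                       years = 2020, seed = 3)
  region <- generate_region(cfg)
  expect_equal(nrow(region$districts), 1)
  expect_equal(unique(region$population$district_id), "D001")
  expect_true(all(region$population$pop >= 0))
})

test_that("region generation is deterministic under a fixed seed", {
  r1 <- generate_region(small_config())
  r2 <- generate_region(small_config())
  expect_identical(r1$districts, r2$districts)
  expect_identical(r1$population, r2$population)
  expect_identical(r1$stations, r2$stations)
})

test_that("invalid region configurations are rejected", {
  expect_error(region_config(n_states = 5, n_districts = 3), "n_districts")
  expect_error(region_config(heat_island_amplitude = -1), "heat_island")
  expect_error(region_config(bbox = c(10, 6, 47, 55)), "bbox")
})

test_that("generated age pyramid matches the requested old-age share", {
  region <- generate_region(region_config(n_districts = 20, n_states = 4,
                                          years = 2020, old_age_share = 0.25,
                                          seed = 5))
  pop <- region$population
  lower <- as.numeric(sub("[-+].*$", "", pop$age_band))
  share <- sum(pop$pop[pop$year == 2020 & lower >= 75]) /
    sum(pop$pop[pop$year == 2020])
  expect_lt(abs(share - 0.25), 0.02)
})

test_that("district coordinates stay inside the bounding box", {
  region <- small_region()
  bbox <- region$config$bbox
  expect_true(all(region$districts$lon >= bbox[1] & region$districts$lon <= bbox[2]))
  expect_true(all(region$districts$lat >= bbox[3] & region$districts$lat <= bbox[4]))
  expect_true(all(table(region$districts$state_id) >= 1))
})

test_that("heat island offsets vanish at zero amplitude and only urban districts warm", {
  cfg <- region_config(n_states = 2, n_districts = 6, n_stations = 3,
                       years = 2020, seed = 9, heat_island_amplitude = 0)
  region <- generate_region(cfg)
  expect_true(all(region$districts$heat_island_c == 0))
  cfg2 <- region_config(n_states = 2, n_districts = 6, n_stations = 3,
                        years = 2020, seed = 9, heat_island_amplitude = 3,
                        urban_fraction = 0.5)
  region2 <- generate_region(cfg2)
  expect_true(all(region2$districts$heat_island_c[!region2$districts$urban] == 0))
  expect_true(all(region2$districts$heat_island_c[region2$districts$urban] > 0))
})

test_that("zero AR coefficient and zero noise give a pure seasonal field", {
  cfg <- region_config(n_states = 1, n_districts = 2, n_stations = 2,
                       years = 2019, seed = 2, ar_sigma_c = 0,
                       station_sigma_c = 0, heat_island_amplitude = 0)
  wx <- generate_temperature_fields(generate_region(cfg))
  one <- wx$district_temps |> dplyr::filter(district_id == "D001")
  # symmetric around the mid-July peak (doy 196)
  doy <- as.numeric(format(one$date, "%j"))
  peak <- one$tmean_c[doy == 196]
  expect_equal(one$tmean_c[doy == 196 - 30], one$tmean_c[doy == 196 + 30],
               tolerance = 1e-10)
  expect_true(all(one$tmean_c <= peak + 1e-12))
})

test_that("AR(1) anomaly reproduces its nominal lag-1 autocorrelation", {
  cfg <- region_config(n_states = 1, n_districts = 1, n_stations = 1,
                       years = 2011:2020, seed = 21, ar_phi = 0.7,
                       ar_sigma_c = 2)
  wx <- generate_temperature_fields(generate_region(cfg))
  a <- wx$anomaly$anomaly_c
  rho <- cor(a[-1], a[-length(a)])
  expect_lt(abs(rho - 0.7), 0.05)
})

test_that("temperature generation is deterministic and aligned across products", {
  w1 <- generate_temperature_fields(small_region())
  w2 <- generate_temperature_fields(small_region())
  expect_identical(w1$district_temps, w2$district_temps)
  expect_identical(w1$station_temps, w2$station_temps)
  expect_setequal(unique(w1$district_temps$date), unique(w1$station_temps$date))
})

test_that("zero-slope risk model gives expected = baseline x population and zero excess", {
  region <- small_region()
  wx <- small_weather()
  truth0 <- generate_mortality_counts(region, wx$district_temps,
                                      true_risk_model(slope = 0,
                                                      dow_factors = rep(1, 7)),
                                      baseline_spec())
  expect_equal(sum(truth0$deaths$excess_true), 0)
  # expected equals baseline x population exactly: check one stratum
  pop <- interpolate_population_daily(region$population,
                                      unique(truth0$deaths$date))
  j <- truth0$deaths |>
    dplyr::filter(district_id == "D001", sex == "f", age_band == "85-90") |>
    dplyr::left_join(pop, by = c("date", "district_id", "sex", "age_band"))
  bl <- baseline_spec()
  b <- bl |> dplyr::filter(sex == "f", age_band == "85-90")
  tau <- as.numeric(j$date - min(j$date)) / 365.25
  expect_equal(j$expected,
               exp(b$log_daily_rate0 + b$trend_per_year * tau) * j$pop,
               tolerance = 1e-12)
})

test_that("realized deaths are non-negative integers close to expectation in total", {
  truth <- small_truth()
  expect_true(all(truth$deaths$deaths >= 0))
  expect_true(all(truth$deaths$deaths == round(truth$deaths$deaths)))
  tot_exp <- sum(truth$deaths$expected)
  tot_obs <- sum(truth$deaths$deaths)
  expect_lt(abs(tot_obs - tot_exp), 4 * sqrt(tot_exp))
})

test_that("realized totals converge to expected totals at root-N rate", {
  # two sizes: z-scores stay bounded while absolute deviation grows ~ sqrt(N)
  for (years in list(2020, 2019:2020)) {
    cfg <- region_config(n_states = 2, n_districts = 4, n_stations = 3,
                         years = years, seed = 17)
    region <- generate_region(cfg)
    wx <- generate_temperature_fields(region)
    truth <- generate_mortality_counts(region, wx$district_temps,
                                       true_risk_model(), baseline_spec())
    z <- (sum(truth$deaths$deaths) - sum(truth$deaths$expected)) /
      sqrt(sum(truth$deaths$expected))
    expect_lt(abs(z), 4)
  }
})

test_that("true excess is non-negative and zero when all lagged temps are capped", {
  truth <- small_truth()
  expect_true(all(truth$deaths$excess_true >= -1e-12))
  # days whose whole lag window is below the cap have exactly zero excess
  tm <- truth$district_temps |> dplyr::arrange(district_id, date)
  cold_keys <- tm |>
    dplyr::group_by(district_id) |>
    dplyr::mutate(warm_in_window = vapply(seq_along(date), function(t) {
      any(tmean_c[max(1, t - 7):t] > 20)
    }, logical(1))) |>
    dplyr::ungroup() |>
    dplyr::filter(!warm_in_window) |>
    dplyr::select(district_id, date)
  ex <- truth$deaths |>
    dplyr::semi_join(cold_keys, by = c("district_id", "date"))
  expect_true(all(ex$excess_true == 0))
})

test_that("zero population in a stratum yields zero deaths always", {
  region <- small_region()
  region$population$pop[region$population$district_id == "D002"] <- 0
  wx <- small_weather()
  truth <- generate_mortality_counts(region, wx$district_temps,
                                     true_risk_model(), baseline_spec())
  d2 <- truth$deaths |> dplyr::filter(district_id == "D002")
  expect_true(all(d2$expected == 0))
  expect_true(all(d2$deaths == 0))
})
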