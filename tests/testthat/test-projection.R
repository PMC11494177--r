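proj_setup <- function() {
  cached("proj_setup", {
    region <- small_region()
    cfg0 <- small_config()
    cfg0$station_sigma_c <- 0
    wx <- generate_temperature_fields(region, cfg0, grid_res = 3)
    interp <- temp_interpolator(region$districts, wx$grid_points)
    st <- heatmort:::stratum_table()
    groups <- unique(st$group)
    params <- exposure_params(
      inner_weights = matrix(0.25 / 4, 1, 4), inner_bias = -5,
      mix_weights = 0.1, mix_bias = 0.9)
    inst <- list(response = stats::setNames(rep(list(params), 8), groups),
                 baseline = baseline_spec(), dow_factors = rep(1, 7), seed = 1L)
    fit <- structure(
      list(instances = list(inst),
           config = train_config(train_years = 2019, validation_years = 2020,
                                 ensemble_size = 1, l = 3, d = 1),
           districts = region$districts, population = region$population,
           ref_date = as.Date("2019-01-01"), groups = groups,
           fit_report = tibble::tibble()),
      class = "exposure_fit")
    list(region = region, wx = wx, interp = interp, fit = fit)
  })
}

test_that("identical members give zero band width and the single trajectory", {
  s <- proj_setup()
  ens <- simulate_climate_ensemble(s$region, years = 2021, n_members = 1,
                                   warming_c_per_decade = 0, grid_res = 3,
                                   seed = 2)
  ens3 <- climate_ensemble(rep(ens$members, 3), ens$points, "triple")
  ps <- project_scenario(s$fit, s$interp, ens3)
  expect_equal(ps$summary$p10, ps$summary$median)
  expect_equal(ps$summary$p90, ps$summary$median)
})

test_that("members below the cap everywhere produce zero excess", {
  s <- proj_setup()
  ens <- simulate_climate_ensemble(s$region, years = 2021, n_members = 2,
                                   warming_c_per_decade = 0, grid_res = 3,
                                   seed = 3)
  cold_members <- lapply(ens$members, function(m) {
    m |> dplyr::mutate(tmean_c = pmin(tmean_c, 10))
  })
  ps <- project_scenario(s$fit, s$interp,
                         climate_ensemble(cold_members, ens$points, "cold"))
  expect_true(all(ps$summary$median == 0))
  expect_true(all(ps$by_member$excess == 0))
})

test_that("member percentiles equal the sort-based order-statistics oracle", {
  s <- proj_setup()
  ens <- simulate_climate_ensemble(s$region, years = 2021, n_members = 50,
                                   grid_res = 3, seed = 4)
  ps <- project_scenario(s$fit, s$interp, ens)
  vals <- ps$by_member$excess[order(ps$by_member$member)]
  # oracle: linear interpolation between order statistics (type 7)
  srt <- sort(vals)
  oracle_q <- function(p) {
    h <- (length(srt) - 1) * p + 1
    lo <- floor(h)
    srt[lo] + (h - lo) * (srt[min(lo + 1, length(srt))] - srt[lo])
  }
  expect_equal(ps$summary$median, oracle_q(0.5), tolerance = 1e-12)
  expect_equal(ps$summary$p10, oracle_q(0.1), tolerance = 1e-12)
  expect_equal(ps$summary$p90, oracle_q(0.9), tolerance = 1e-12)
  expect_true(all(ps$summary$p10 <= ps$summary$median &
                    ps$summary$median <= ps$summary$p90))

  # invariance to member ordering
  perm <- sample(length(ens$members))
  ps2 <- project_scenario(s$fit, s$interp,
                          climate_ensemble(ens$members[perm], ens$points,
                                           ens$scenario))
  expect_equal(ps2$summary, ps$summary)
})

test_that("uniform warming never decreases projected excess for a monotone response", {
  s <- proj_setup()
  ens <- simulate_climate_ensemble(s$region, years = 2021, n_members = 3,
                                   grid_res = 3, seed = 6)
  warm_members <- lapply(ens$members, function(m) {
    m |> dplyr::mutate(tmean_c = tmean_c + 1)
  })
  ps0 <- project_scenario(s$fit, s$interp, ens)
  ps1 <- project_scenario(s$fit, s$interp,
                          climate_ensemble(warm_members, ens$points, "warmer"))
  expect_true(all(ps1$summary$median >= ps0$summary$median))
})

test_that("static projection reproduces historical attribution on identical inputs", {
  s <- proj_setup()
  # a one-member "ensemble" whose downscaled temps we also attribute directly
  ens <- simulate_climate_ensemble(s$region, years = 2021, n_members = 1,
                                   grid_res = 3, seed = 8)
  ps <- project_scenario(s$fit, s$interp, ens, freeze_year = 2020)
  dts <- downscale_climate_member(s$interp, ens$members[[1]])
  pop_static <- s$region$population |> dplyr::filter(year == 2020)
  exc <- suppressWarnings(excess_mortality(
    s$fit, dts, pop_static, level = "national_day",
    dow_correct = FALSE, baseline_freeze_date = as.Date("2020-12-31")))
  expect_equal(ps$by_member$excess, sum(exc$excess), tolerance = 1e-9)
})

test_that("demographic scenarios preserve national totals and fixed shares", {
  region <- small_region()
  base <- region$population
  # projection equal to the base-year national totals leaves populations unchanged
  nat <- base |> dplyr::filter(year == 2020) |>
    dplyr::group_by(sex, age_band) |>
    dplyr::summarise(pop = sum(pop), .groups = "drop") |>
    dplyr::mutate(year = 2030)
  scaled <- apply_demographic_scenario(base, nat, base_year = 2020)
  ref <- base |> dplyr::filter(year == 2020) |>
    dplyr::arrange(district_id, sex, age_band)
  cmp <- scaled |> dplyr::arrange(district_id, sex, age_band)
  expect_equal(cmp$pop, ref$pop, tolerance = 1e-12)

  # doubling the national 85+ bands doubles them in every district
  nat2 <- nat |>
    dplyr::mutate(pop = ifelse(age_band %in% c("85-90", "90-95", "95+"),
                               2 * pop, pop))
  scaled2 <- apply_demographic_scenario(base, nat2, base_year = 2020)
  j <- scaled2 |>
    dplyr::left_join(ref |> dplyr::select(district_id, sex, age_band,
                                          pop_base = pop),
                     by = c("district_id", "sex", "age_band"))
  old <- j$age_band %in% c("85-90", "90-95", "95+")
  expect_equal(j$pop[old], 2 * j$pop_base[old], tolerance = 1e-12)
  expect_equal(j$pop[!old], j$pop_base[!old], tolerance = 1e-12)

  # random projection: district sums match the national projection exactly
  set.seed(77)
  nat3 <- nat |> dplyr::mutate(pop = pop * runif(dplyr::n(), 0.5, 2))
  scaled3 <- apply_demographic_scenario(base, nat3, base_year = 2020)
  sums <- scaled3 |>
    dplyr::group_by(sex, age_band) |>
    dplyr::summarise(pop = sum(pop), .groups = "drop") |>
    dplyr::arrange(sex, age_band)
  expect_equal(sums$pop, nat3 |> dplyr::arrange(sex, age_band) |> dplyr::pull(pop),
               tolerance = 1e-9)
})
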