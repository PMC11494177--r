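# Climate-scenario projection: downscale each ensemble member to districts
# with the fitted attention interpolator (no bias correction), run the fitted
# exposure ensemble under the capped counterfactual with frozen population
# and baseline, and summarise annual excess across members.

#' Container for a climate-projection temperature ensemble
#'
#' @param members List of long tibbles (`point_id`, `date`, `tmean_c`), one
#'   per ensemble member; all members must share calendar and grid.
#' @param points Tibble `point_id`, `lon`, `lat` of the grid.
#' @param scenario Scenario label (e.g. `"ssp245"`).
#' @return Object of class `climate_ensemble`.
#' @export
climate_ensemble <- function(members, points, scenario = "scenario") {
  assert_that(length(members) >= 1, "at least one member required")
  ref_pts <- sort(unique(members[[1]]$point_id))
  ref_dates <- sort(unique(members[[1]]$date))
  for (m in members) {
    assert_that(setequal(unique(m$point_id), ref_pts) &&
                  setequal(unique(m$date), ref_dates),
                "all members must share calendar and grid")
  }
  assert_that(all(ref_pts %in% points$point_id),
              "points table does not cover the members' grid")
  structure(list(members = members, points = points, scenario = scenario),
            class = "climate_ensemble")
}

#' @export
print.climate_ensemble <- function(x, ...) {
  cat(sprintf("<climate_ensemble> '%s': %d members, %d grid points, %d days\n",
              x$scenario, length(x$members), length(unique(x$members[[1]]$point_id)),
              length(unique(x$members[[1]]$date))))
  invisible(x)
}

#' Simulate a synthetic climate-projection ensemble
#'
#' Builds members around the synthetic region's noise-free grid field: each
#' member adds an independent AR(1) anomaly and a linear warming trend, so
#' the ensemble has known spread and a controllable climate signal.
#'
#' @param region A [generate_region()] result.
#' @param years Calendar years of the projection.
#' @param n_members Number of members (default 50).
#' @param warming_c_per_decade Linear trend added over the projection period.
#' @param grid_res Grid spacing in degrees (default 2).
#' @param scenario Scenario label.
#' @param seed Integer seed.
#' @return A [climate_ensemble()].
#' @export
simulate_climate_ensemble <- function(region, years, n_members = 50,
                                      warming_c_per_decade = 0.3,
                                      grid_res = 2, scenario = "ssp-sim",
                                      seed = 1L) {
  cfg <- region$config
  cfg$years <- as.integer(years)
  cfg$ar_sigma_c <- 0 # base field without weather noise; members add their own
  wx <- generate_temperature_fields(region, cfg, grid_res = grid_res)
  base <- series_matrix(wx$grid_temps, "point_id")
  dates <- attr(base, "dates")
  nt <- ncol(base)
  trend <- warming_c_per_decade * (as.numeric(dates - dates[1]) / 3652.5)
  members <- with_seed(child_seed(seed, 7), {
    lapply(seq_len(n_members), function(m) {
      anom <- ar1_series(nt, region$config$ar_phi, region$config$ar_sigma_c)
      mm <- base + rep(anom + trend, each = nrow(base))
      attributes(mm) <- attributes(base)
      matrix_to_series(mm, "point_id")
    })
  })
  climate_ensemble(members, wx$grid_points, scenario)
}

#' Project heat-related excess mortality under a climate ensemble
#'
#' For each member: downscale the grid temperatures to districts with the
#' fitted interpolator, compute annual excess deaths through the capped
#' counterfactual with population and baseline frozen at a reference date,
#' then summarise each year across members by the median and the empirical
#' 10th/90th percentiles (linear interpolation between order statistics).
#'
#' @param fit A fitted [train_ensemble()] ensemble.
#' @param interpolator A `temp_interpolator` fitted with the ensemble's grid
#'   points as sources.
#' @param ensemble A [climate_ensemble()].
#' @param population Annual snapshots; with `population_mode = "static"` the
#'   snapshot of `freeze_year` is held constant.
#' @param cap_c Attribution cap in degrees Celsius (default 20).
#' @param freeze_year Year whose population snapshot and end-of-year baseline
#'   are held fixed; defaults to the latest snapshot year.
#' @param population_mode `"static"` (default; constant population and
#'   baseline) or `"interpolated"` (population follows the snapshots).
#' @param dow_correct Apply fitted day-of-week factors (default `FALSE` for
#'   projections).
#' @return Object of class `projection_summary`: `summary` tibble (`year`,
#'   `median`, `p10`, `p90`, `per_million_median`), `by_member` tibble
#'   (`member`, `year`, `excess`), and metadata.
#' @export
project_scenario <- function(fit, interpolator, ensemble,
                             population = fit$population,
                             cap_c = 20, freeze_year = NULL,
                             population_mode = c("static", "interpolated"),
                             dow_correct = FALSE) {
  population_mode <- match.arg(population_mode)
  assert_that(inherits(ensemble, "climate_ensemble"),
              "ensemble must be a climate_ensemble")
  grid_ids <- sort(unique(ensemble$members[[1]]$point_id))
  assert_that(setequal(grid_ids, interpolator$sources$source_id),
              "member grid does not match the interpolator's source grid")
  freeze_year <- freeze_year %||% max(population$year)
  freeze_date <- as.Date(sprintf("%d-12-31", freeze_year))
  pop <- if (population_mode == "static") {
    population |> filter(.data$year == freeze_year)
  } else {
    population
  }

  by_member <- imap(ensemble$members, function(member, m) {
    dts <- downscale_climate_member(interpolator, member)
    exc <- suppressWarnings(
      excess_mortality(fit, dts, pop, cap_c = cap_c, level = "national_day",
                       dow_correct = dow_correct,
                       baseline_freeze_date = freeze_date)
    )
    exc |>
      mutate(year = as.integer(format(.data$date, "%Y"))) |>
      group_by(.data$year) |>
      summarise(excess = sum(.data$excess), .groups = "drop") |>
      mutate(member = m)
  }) |> bind_rows()

  pop_total <- sum(pop$pop[pop$year == max(pop$year)])
  summary <- by_member |>
    group_by(.data$year) |>
    summarise(
      median = median(.data$excess),
      p10 = quantile(.data$excess, 0.1, names = FALSE),
      p90 = quantile(.data$excess, 0.9, names = FALSE),
      .groups = "drop"
    ) |>
    mutate(per_million_median = .data$median / pop_total * 1e6)

  structure(
    list(summary = summary, by_member = by_member,
         scenario = ensemble$scenario, cap_c = cap_c,
         freeze_year = freeze_year, population_mode = population_mode,
         pop_total = pop_total),
    class = "projection_summary"
  )
}

#' @export
print.projection_summary <- function(x, ...) {
  cat(sprintf("<projection_summary> '%s', %d members, years %d-%d\n",
              x$scenario, length(unique(x$by_member$member)),
              min(x$summary$year), max(x$summary$year)))
  last <- x$summary[which.max(x$summary$year), ]
  cat(sprintf("  final year median %.0f excess deaths (10th-90th: %.0f-%.0f)\n",
              last$median, last$p10, last$p90))
  invisible(x)
}

#' @export
tidy.projection_summary <- function(x, ...) x$summary

#' @export
glance.projection_summary <- function(x, ...) {
  decade <- x$summary |> filter(.data$year > max(.data$year) - 10)
  first_dec <- x$summary |> filter(.data$year <= min(.data$year) + 9)
  tibble(
    scenario = x$scenario,
    n_members = length(unique(x$by_member$member)),
    last_decade_median = median(decade$median),
    first_decade_median = median(first_dec$median),
    factor_vs_start = median(decade$median) / max(median(first_dec$median), 1e-12)
  )
}

#' Scale district populations to a national demographic projection
#'
#' District populations for future years are the national per-age-band
#' projection allocated to districts by each band's base-year geographical
#' shares, so district sums match the national projection exactly.
#'
#' @param populations_base Snapshot tibble (`district_id`, `sex`, `age_band`,
#'   `year`, `pop`) containing `base_year`.
#' @param national_projection Tibble `year`, `age_band`, optional `sex`, `pop`
#'   — national totals per band (and sex, if given) for future years.
#' @param base_year Year whose geographical distribution is held fixed.
#' @return Tibble `district_id`, `sex`, `age_band`, `year`, `pop` for the
#'   projection years.
#' @export
apply_demographic_scenario <- function(populations_base, national_projection,
                                       base_year) {
  base <- populations_base |> filter(.data$year == base_year)
  assert_that(nrow(base) > 0, "base_year not present in populations_base")
  by_sex <- "sex" %in% names(national_projection)
  keys <- if (by_sex) c("sex", "age_band") else "age_band"
  miss <- setdiff(unique(national_projection$age_band), unique(base$age_band))
  assert_that(length(miss) == 0,
              sprintf("age bands absent from the base population: %s",
                      paste(miss, collapse = ", ")))

  shares <- base |>
    group_by(across(dplyr::all_of(c("district_id", keys)))) |>
    summarise(pop = sum(.data$pop), .groups = "drop") |>
    group_by(across(dplyr::all_of(keys))) |>
    mutate(share = .data$pop / sum(.data$pop)) |>
    ungroup() |>
    select(-"pop")

  national_projection |>
    rename(pop_national = "pop") |>
    left_join(shares, by = keys, relationship = "many-to-many") |>
    mutate(pop = .data$pop_national * .data$share) |>
    select(dplyr::any_of(c("district_id", "sex", "age_band", "year", "pop")))
}
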