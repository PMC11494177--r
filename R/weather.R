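#' Generate daily temperature fields for the synthetic region
#'
#' Builds daily mean temperatures as
#' seasonal sinusoid (peak around 15 July) + smooth spatial gradient +
#' regionally shared AR(1) weather anomaly + constant per-district urban
#' heat-island offset, plus independent measurement noise at the stations.
#' District series are the noise-free "truth"; station series observe the
#' field at the station location (no heat island) with Gaussian noise; an
#' optional regular grid samples the same noise-free field.
#'
#' @param region A [generate_region()] result.
#' @param config A [region_config()]; defaults to `region$config`.
#' @param grid_res Grid spacing in degrees for the auxiliary gridded product
#'   (emulating a reanalysis); `NULL` skips the grid.
#' @return A list of class `synthetic_weather` with tibbles
#'   `district_temps` (`district_id`, `date`, `tmean_c`),
#'   `station_temps` (`station_id`, `date`, `tmean_c`),
#'   `grid_temps` (`point_id`, `lon`, `lat`, `date`, `tmean_c`) or `NULL`,
#'   the shared daily `anomaly`, and `grid_points`.
#' @examples
#' region <- generate_region(region_config(n_districts = 4, n_states = 2,
#'                                         years = 2019, n_stations = 5))
#' wx <- generate_temperature_fields(region)
#' range(wx$district_temps$tmean_c)
#' @export
generate_temperature_fields <- function(region, config = region$config,
                                        grid_res = NULL) {
  dates <- year_dates(config$years)
  assert_that(length(dates) > 0, "empty date range")
  with_seed(child_seed(config$seed, 2), {
    nt <- length(dates)
    anomaly <- ar1_series(nt, config$ar_phi, config$ar_sigma_c)

    field_at <- function(lon, lat) {
      # n_points x n_days matrix of the noise-free field
      seasonal <- seasonal_cycle(dates, config$mean_temp_c, config$seasonal_amp_c)
      grad <- config$lon_gradient_c_per_deg * (lon - mean(config$bbox[1:2])) +
        config$lat_gradient_c_per_deg * (lat - mean(config$bbox[3:4]))
      outer(grad, seasonal + anomaly, `+`)
    }

    dm <- field_at(region$districts$lon, region$districts$lat) +
      region$districts$heat_island_c
    rownames(dm) <- region$districts$district_id
    colnames(dm) <- as.character(dates)
    attr(dm, "dates") <- dates

    sm <- field_at(region$stations$lon, region$stations$lat) +
      rnorm(nrow(region$stations) * nt, 0, config$station_sigma_c)
    rownames(sm) <- region$stations$station_id
    colnames(sm) <- as.character(dates)
    attr(sm, "dates") <- dates

    grid_points <- NULL
    grid_temps <- NULL
    if (!is.null(grid_res)) {
      lons <- seq(config$bbox[1], config$bbox[2], by = grid_res)
      lats <- seq(config$bbox[3], config$bbox[4], by = grid_res)
      grid_points <- expand_grid(lon = lons, lat = lats)
      grid_points$point_id <- sprintf("G%03d", seq_len(nrow(grid_points)))
      gm <- field_at(grid_points$lon, grid_points$lat)
      rownames(gm) <- grid_points$point_id
      colnames(gm) <- as.character(dates)
      attr(gm, "dates") <- dates
      grid_temps <- matrix_to_series(gm, "point_id") |>
        left_join(grid_points, by = "point_id") |>
        select("point_id", "lon", "lat", "date", "tmean_c")
    }

    structure(
      list(
        district_temps = matrix_to_series(dm, "district_id"),
        station_temps = matrix_to_series(sm, "station_id"),
        grid_temps = grid_temps,
        grid_points = grid_points,
        anomaly = tibble(date = dates, anomaly_c = anomaly),
        config = config
      ),
      class = "synthetic_weather"
    )
  })
}

# annual sinusoid peaking on day-of-year 196 (~15 July)
seasonal_cycle <- function(dates, mean_c, amp_c) {
  doy <- as.numeric(format(dates, "%j"))
  mean_c + amp_c * cos(2 * pi * (doy - 196) / 365.25)
}

# stationary AR(1) with marginal variance sigma^2/(1 - phi^2)
ar1_series <- function(n, phi, sigma) {
  if (sigma == 0) return(numeric(n))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sigma / sqrt(1 - phi^2))
  innov <- rnorm(n - 1, 0, sigma)
  for (t in seq_len(n - 1)) x[t + 1] <- phi * x[t] + innov[t]
  x
}
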