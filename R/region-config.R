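#' Configuration of the synthetic study region
#'
#' Describes a self-contained synthetic study region: an administrative
#' hierarchy of states and districts, a station network, and the statistical
#' structure of its weather. The defaults emulate a German-like setting at a
#' reduced scale: around 200,000 inhabitants per district, a quarter of
#' districts urban with a constant heat-island offset, a seasonal temperature
#' cycle peaking in mid-July with a shared AR(1) weather anomaly, and noisy
#' station thermometers.
#'
#' @param n_states Number of federal states (>= 1).
#' @param n_districts Number of districts (>= `n_states`); each state gets at
#'   least one district.
#' @param n_stations Number of weather stations scattered over the bounding box.
#' @param bbox Numeric vector `c(lon_min, lon_max, lat_min, lat_max)` in degrees.
#' @param urban_fraction Proportion of districts flagged urban, in `[0, 1]`.
#' @param heat_island_amplitude Maximum constant urban heat-island offset in
#'   degrees Celsius (>= 0); urban districts draw an offset between 30% and
#'   100% of it.
#' @param years Inclusive calendar-year range covered by the simulation,
#'   e.g. `2015:2020`.
#' @param seed Integer seed; all generator stages derive their randomness from it.
#' @param old_age_share Target national share of the population aged 75+,
#'   in `[0, 0.6]`.
#' @param mean_temp_c,seasonal_amp_c Level and semi-amplitude of the seasonal
#'   sinusoid (degrees Celsius); the cycle peaks around 15 July.
#' @param lat_gradient_c_per_deg,lon_gradient_c_per_deg Smooth spatial gradient
#'   of the mean field, degrees Celsius per degree of latitude / longitude.
#' @param ar_phi,ar_sigma_c AR(1) coefficient and innovation standard deviation
#'   (degrees Celsius) of the regionally shared daily weather anomaly.
#' @param station_sigma_c Independent station measurement noise s.d. in degrees
#'   Celsius.
#'
#' @return An object of class `region_config` (a named list).
#' @export
region_config <- function(n_states = 4,
                          n_districts = 20,
                          n_stations = 30,
                          bbox = c(6, 15, 47, 55),
                          urban_fraction = 0.25,
                          heat_island_amplitude = 2,
                          years = 2015:2020,
                          seed = 1L,
                          old_age_share = 0.12,
                          mean_temp_c = 9.5,
                          seasonal_amp_c = 10,
                          lat_gradient_c_per_deg = -0.6,
                          lon_gradient_c_per_deg = 0.1,
                          ar_phi = 0.7,
                          ar_sigma_c = 2.2,
                          station_sigma_c = 0.5) {
  cfg <- list(
    n_states = as.integer(n_states), n_districts = as.integer(n_districts),
    n_stations = as.integer(n_stations), bbox = as.numeric(bbox),
    urban_fraction = urban_fraction,
    heat_island_amplitude = heat_island_amplitude,
    years = as.integer(years), seed = as.integer(seed),
    old_age_share = old_age_share,
    mean_temp_c = mean_temp_c, seasonal_amp_c = seasonal_amp_c,
    lat_gradient_c_per_deg = lat_gradient_c_per_deg,
    lon_gradient_c_per_deg = lon_gradient_c_per_deg,
    ar_phi = ar_phi, ar_sigma_c = ar_sigma_c,
    station_sigma_c = station_sigma_c
  )
  class(cfg) <- "region_config"
  validate_region_config(cfg)
  cfg
}

validate_region_config <- function(cfg) {
  assert_that(cfg$n_states >= 1L, "n_states must be >= 1")
  assert_that(cfg$n_districts >= cfg$n_states,
              "n_districts must be >= n_states")
  assert_that(cfg$n_stations >= 1L, "n_stations must be >= 1")
  assert_that(length(cfg$bbox) == 4 && cfg$bbox[2] > cfg$bbox[1] &&
                cfg$bbox[4] > cfg$bbox[3],
              "bbox must be c(lon_min, lon_max, lat_min, lat_max), non-degenerate")
  assert_that(cfg$urban_fraction >= 0 && cfg$urban_fraction <= 1,
              "urban_fraction must be in [0, 1]")
  assert_that(cfg$heat_island_amplitude >= 0,
              "heat_island_amplitude must be >= 0")
  assert_that(length(cfg$years) >= 1, "years must be non-empty")
  assert_that(cfg$old_age_share >= 0 && cfg$old_age_share <= 0.6,
              "old_age_share must be in [0, 0.6]")
  assert_that(abs(cfg$ar_phi) < 1, "ar_phi must satisfy |phi| < 1")
  invisible(cfg)
}

#' @export
print.region_config <- function(x, ...) {
  cat(sprintf(
    "<region_config> %d states / %d districts / %d stations, years %d-%d, seed %d\n",
    x$n_states, x$n_districts, x$n_stations, min(x$years), max(x$years), x$seed))
  invisible(x)
}
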