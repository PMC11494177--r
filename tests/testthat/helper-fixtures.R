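# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_config <- function(...) {
  region_config(n_states = 2, n_districts = 4, n_stations = 6,
                years = 2019:2020, seed = 11, ...)
}

small_region <- function() cached("small_region", generate_region(small_config()))

small_weather <- function() {
  cached("small_weather", generate_temperature_fields(small_region()))
}

small_truth <- function() {
  cached("small_truth", generate_mortality_counts(
    small_region(), small_weather()$district_temps,
    true_risk_model(), baseline_spec()))
}

small_streams <- function() cached("small_streams", build_reporting_tables(small_truth()))

# one-district constant-temperature toy series
toy_temps <- function(values, start = as.Date("2020-01-01"), id = "D1") {
  tibble::tibble(district_id = id, date = start + seq_along(values) - 1,
                 tmean_c = values)
}
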