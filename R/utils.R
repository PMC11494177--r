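# Numeric and calendar helpers shared across modules.

softplus <- function(x) {
  # log(1 + e^x), stable for large |x|
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

softplus_inv <- function(y) {
  # inverse of softplus on y > 0; y == 0 maps to a large negative value
  # (softplus(-40) ~ 4e-18, indistinguishable from 0 at double precision)
  ifelse(y <= 0, -40, ifelse(y > 30, y, log(expm1(pmax(y, 1e-17)))))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# Deterministic child seed: keeps everything derived from one user seed while
# decoupling the streams of the different generator stages. Stays < 2^31.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Sequence of calendar dates covering whole years
#' @noRd
year_dates <- function(years) {
  years <- sort(unique(as.integer(years)))
  seq(as.Date(sprintf("%d-01-01", min(years))),
      as.Date(sprintf("%d-12-31", max(years))), by = "day")
}

# ISO-8601 week labels; a week is identified by (iso_year, iso_week)
iso_week_key <- function(dates) {
  sprintf("%04d-W%02d", lubridate::isoyear(dates), lubridate::isoweek(dates))
}

# Day-of-week index 1..7 (Monday = 1), proleptic Gregorian
weekday_index <- function(dates) {
  lubridate::wday(dates, week_start = 1)
}

#' Convert a long (series_id, date, value) tibble to a series x day matrix
#' @noRd
series_matrix <- function(tbl, id_col, value_col = "tmean_c") {
  ids <- sort(unique(tbl[[id_col]]))
  dates <- sort(unique(tbl$date))
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(dates),
              dimnames = list(ids, as.character(dates)))
  m[cbind(match(tbl[[id_col]], ids), match(tbl$date, dates))] <- tbl[[value_col]]
  attr(m, "dates") <- dates
  m
}

matrix_to_series <- function(m, id_col, value_col = "tmean_c") {
  dates <- attr(m, "dates") %||% as.Date(colnames(m))
  out <- tibble(
    !!id_col := rep(rownames(m), times = ncol(m)),
    date = rep(dates, each = nrow(m)),
    !!value_col := as.vector(m)
  )
  out
}

# Great-circle distance in km between one point and a matrix of points
haversine_km <- function(lon, lat, lon_j, lat_j) {
  geosphere::distHaversine(c(lon, lat), cbind(lon_j, lat_j)) / 1000
}
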