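#' Interpolate annual population snapshots to daily values
#'
#' Population snapshots are taken on 31 December of each year; daily values are
#' linear interpolations between consecutive snapshots and constant beyond the
#' first/last snapshot (with a warning when extrapolating).
#'
#' @param snapshots Tibble with columns `district_id`, `sex`, `age_band`,
#'   `year`, `pop` (31-December values), e.g. `region$population`.
#' @param dates Vector of `Date`s at which to evaluate.
#' @return Tibble `date`, `district_id`, `sex`, `age_band`, `pop`.
#' @examples
#' snaps <- tidyr::expand_grid(district_id = "D1", sex = "f", age_band = "70-75",
#'                             year = 2019:2020)
#' snaps$pop <- c(1000, 2000)
#' interpolate_population_daily(snaps, as.Date("2020-07-01"))
#' @export
interpolate_population_daily <- function(snapshots, dates) {
  assert_that(nrow(snapshots) >= 1, "snapshots must be non-empty")
  dates <- sort(unique(as.Date(dates)))
  keys <- snapshots |> distinct(.data$district_id, .data$sex, .data$age_band)
  arr <- pop_matrix(snapshots, dates)
  tibble(
    date = rep(dates, each = nrow(keys)),
    district_id = rep(keys$district_id, times = length(dates)),
    sex = rep(keys$sex, times = length(dates)),
    age_band = rep(keys$age_band, times = length(dates)),
    pop = as.vector(arr$values)
  )
}

# internal: interpolate all (district, sex, age) series at once.
# Returns list(keys, values = n_keys x n_dates matrix).
pop_matrix <- function(snapshots, dates) {
  snap_dates <- as.Date(sprintf("%d-12-31", sort(unique(snapshots$year))))
  xs <- as.numeric(snap_dates)
  keys <- snapshots |> distinct(.data$district_id, .data$sex, .data$age_band)
  key_id <- paste(snapshots$district_id, snapshots$sex, snapshots$age_band)
  key_ref <- paste(keys$district_id, keys$sex, keys$age_band)
  A <- matrix(NA_real_, nrow = nrow(keys), ncol = length(xs))
  A[cbind(match(key_id, key_ref),
          match(snapshots$year, sort(unique(snapshots$year))))] <- snapshots$pop
  assert_that(!anyNA(A), "snapshots must be complete: every stratum in every year")

  xq <- as.numeric(dates)
  outside <- xq < min(xs) | xq > max(xs)
  if (any(outside)) {
    warn(sprintf("%d date(s) outside the snapshot range: using constant extrapolation",
                 sum(outside)))
  }
  if (length(xs) == 1) {
    values <- A[, rep(1, length(xq)), drop = FALSE]
  } else {
    i1 <- findInterval(xq, xs, rightmost.closed = TRUE)
    i0 <- pmax(i1, 1)
    i1 <- pmin(i0 + 1, length(xs))
    i0 <- pmin(pmax(i1 - 1, 1), length(xs))
    w <- ifelse(xs[i1] == xs[i0], 0, (xq - xs[i0]) / (xs[i1] - xs[i0]))
    w <- pmin(pmax(w, 0), 1) # constant beyond the ends
    values <- A[, i0, drop = FALSE] * rep(1 - w, each = nrow(A)) +
      A[, i1, drop = FALSE] * rep(w, each = nrow(A))
  }
  list(keys = keys, values = values, dates = dates)
}

# internal: array [stratum(40), district, day] in canonical stratum order
pop_array <- function(snapshots, dates, district_ids) {
  st <- stratum_table()
  pm <- pop_matrix(snapshots, dates)
  row_key <- paste(pm$keys$sex, pm$keys$age_band, sep = ":")
  arr <- array(0, dim = c(nrow(st), length(district_ids), length(dates)))
  ridx <- match(row_key, st$stratum)
  didx <- match(pm$keys$district_id, district_ids)
  ok <- !is.na(ridx) & !is.na(didx)
  assert_that(all(ok), "population snapshots contain unknown strata or districts")
  for (i in which(ok)) arr[ridx[i], didx[i], ] <- pm$values[i, ]
  dimnames(arr) <- list(st$stratum, district_ids, as.character(dates))
  arr
}
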