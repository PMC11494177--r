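#' Build the lag matrix of a daily temperature series
#'
#' For each (series, day) the lag vector holds the same-day temperature first,
#' followed by the `l` preceding days: `[T_t, T_{t-1}, ..., T_{t-l}]`. The
#' first `l` days of a series are padded by replicating the first observed day.
#'
#' @param temps Long tibble with columns `date`, a series id column and
#'   `tmean_c`; the calendar must be contiguous (daily, no gaps) per series.
#' @param l Number of lag days (>= 0); lag vectors have length `l + 1`.
#' @param id_col Name of the series id column (default `"district_id"`).
#' @return A numeric matrix with one row per (series, day) and `l + 1` columns
#'   named `lag0 ... lagl`; attributes `ids`, `dates` give the row layout
#'   (rows ordered date-major: all series for day 1, then day 2, ...).
#' @examples
#' x <- tibble::tibble(district_id = "D1",
#'                     date = as.Date("2020-01-01") + 0:2,
#'                     tmean_c = c(10, 20, 30))
#' build_lag_matrix(x, l = 1)
#' @export
build_lag_matrix <- function(temps, l = 7, id_col = "district_id") {
  assert_that(l >= 0, "l must be >= 0")
  m <- series_matrix(temps, id_col)
  dates <- attr(m, "dates")
  if (length(dates) > 1) {
    gaps <- diff(as.integer(dates))
    assert_that(all(gaps == 1), "calendar has gaps: daily series must be contiguous")
  }
  assert_that(!anyNA(m), "temperature series contain missing values")
  lag_matrix_from_mat(m, l)
}

# internal: m is series x day; returns (n_series*n_day) x (l+1), date-major rows
lag_matrix_from_mat <- function(m, l) {
  nd <- nrow(m); nt <- ncol(m)
  L <- matrix(NA_real_, nrow = nd * nt, ncol = l + 1)
  for (k in 0:l) {
    idx <- pmax(seq_len(nt) - k, 1) # replicate-first-day padding
    L[, k + 1] <- as.vector(m[, idx, drop = FALSE])
  }
  colnames(L) <- paste0("lag", 0:l)
  attr(L, "ids") <- rownames(m)
  attr(L, "dates") <- attr(m, "dates")
  L
}
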