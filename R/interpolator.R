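# Attention-weighted spatial interpolation: each district i carries a
# trainable position X_i, bias b_i and positive scale alpha_i, and attends to
# the fixed source points Y_j (weather stations or climate-model grid points):
#
#   T_i(t) = b_i + sum_j w_ij T_j(t),
#   w_ij = exp(-alpha_i d(X_i, Y_j)) / sum_k exp(-alpha_i d(X_i, Y_k)),
#
# with d the great-circle distance in km. The same fitted object serves as a
# statistical downscaler for climate-model members (no bias correction).

#' Construct an attention interpolator
#'
#' @param districts Tibble with `district_id`, `lon`, `lat` — the trainable
#'   district positions (initialised at the reference points), optional
#'   `bias` (degrees Celsius, default 0) and `alpha` (positive scale in 1/km,
#'   default 1).
#' @param sources Tibble with a source id column (`station_id` or `point_id`),
#'   `lon`, `lat` — fixed source-point positions.
#' @return Object of class `temp_interpolator`.
#' @export
temp_interpolator <- function(districts, sources) {
  assert_that(nrow(sources) >= 1, "at least one source point is required")
  id_col <- intersect(c("station_id", "point_id", "source_id"), names(sources))[1]
  assert_that(!is.na(id_col), "sources need a station_id/point_id/source_id column")
  d <- tibble(
    district_id = districts$district_id,
    lon = districts$lon, lat = districts$lat,
    bias = districts[["bias"]] %||% rep(0, nrow(districts)),
    alpha = districts[["alpha"]] %||% rep(1, nrow(districts))
  )
  assert_that(all(d$alpha > 0), "alpha must be positive")
  structure(
    list(
      districts = d,
      sources = tibble(source_id = sources[[id_col]],
                       lon = sources$lon, lat = sources$lat),
      source_id_col = id_col
    ),
    class = "temp_interpolator"
  )
}

#' Attention weights of one district over the source points
#'
#' @param params A [temp_interpolator()].
#' @param district_id District identifier.
#' @return Tibble `source_id`, `distance_km`, `weight`; weights sum to 1.
#' @export
attention_weights <- function(params, district_id) {
  i <- match(district_id, params$districts$district_id)
  assert_that(!is.na(i), sprintf("unknown district '%s'", district_id))
  d <- params$districts[i, ]
  dist <- haversine_km(d$lon, d$lat, params$sources$lon, params$sources$lat)
  w <- softmax_neg(d$alpha * dist)
  tibble(source_id = params$sources$source_id, distance_km = dist, weight = w)
}

softmax_neg <- function(x) {
  e <- exp(-(x - min(x)))
  e / sum(e)
}

# weight matrix: districts x sources
weight_matrix <- function(params) {
  W <- t(vapply(seq_len(nrow(params$districts)), function(i) {
    d <- params$districts[i, ]
    dist <- haversine_km(d$lon, d$lat, params$sources$lon, params$sources$lat)
    softmax_neg(d$alpha * dist)
  }, numeric(nrow(params$sources))))
  rownames(W) <- params$districts$district_id
  colnames(W) <- params$sources$source_id
  W
}

#' Predict district temperatures from source-point observations
#'
#' @param params A [temp_interpolator()].
#' @param source_temps Long tibble with the source id column, `date`,
#'   `tmean_c`; must be complete (no missing values) — fill gaps first, e.g.
#'   with [fill_station_gaps()].
#' @return Tibble `district_id`, `date`, `tmean_c`.
#' @export
predict_district_temperatures <- function(params, source_temps) {
  id_col <- intersect(c(params$source_id_col, "source_id"), names(source_temps))[1]
  assert_that(!is.na(id_col), "source_temps must carry the source id column")
  m <- series_matrix(source_temps, id_col)
  missing_src <- setdiff(params$sources$source_id, rownames(m))
  assert_that(length(missing_src) == 0,
              sprintf("source_temps missing series for: %s",
                      paste(utils::head(missing_src, 5), collapse = ", ")))
  m <- m[params$sources$source_id, , drop = FALSE]
  assert_that(!anyNA(m), "source_temps contain missing values; fill them first")
  W <- weight_matrix(params)
  out <- W %*% m + params$districts$bias
  attr(out, "dates") <- attr(m, "dates")
  matrix_to_series(out, "district_id")
}

#' Fit the attention interpolator against reference district temperatures
#'
#' Minimises the mean squared error between predicted and reference district
#' temperatures over the training portion of an 80:20 temporal split. The
#' objective separates by district (each district owns its position, bias and
#' scale and the source points are fixed), so each district's four parameters
#' (`lon`, `lat`, `bias`, `log alpha` through a softplus) are optimised
#' independently with L-BFGS-B, initialised at the district reference point
#' with bias 0 and alpha 1/km.
#'
#' @param source_temps Long tibble of source observations (id column, `date`,
#'   `tmean_c`), complete on the overlapping calendar.
#' @param reference_temps Long tibble `district_id`, `date`, `tmean_c` — the
#'   reference district series (e.g. from a gridded product).
#' @param districts Tibble `district_id`, `lon`, `lat` of reference points.
#' @param sources Tibble of source positions (id column, `lon`, `lat`).
#' @param train_frac Fraction of the overlapping dates (earliest first) used
#'   for training; the remainder is validation (default 0.8).
#' @param maxit L-BFGS-B iteration cap per district.
#' @return A fitted `temp_interpolator` with a `fit_report` attribute-like
#'   element: tibble `district_id`, `train_rmse_c`, `val_rmse_c`, and overall
#'   `train_rmse_c` / `val_rmse_c` scalars.
#' @export
fit_interpolator <- function(source_temps, reference_temps, districts, sources,
                             train_frac = 0.8, maxit = 200) {
  id_col <- intersect(c("station_id", "point_id", "source_id"), names(sources))[1]
  sm <- series_matrix(source_temps, intersect(c(id_col, "source_id"), names(source_temps))[1])
  rm_ <- series_matrix(reference_temps, "district_id")
  shared <- intersect(as.character(attr(sm, "dates")), as.character(attr(rm_, "dates")))
  assert_that(length(shared) >= 10,
              "source and reference series share fewer than 10 dates")
  sm <- sm[, shared, drop = FALSE]
  rm_ <- rm_[, shared, drop = FALSE]
  assert_that(!anyNA(sm), "source_temps contain missing values on the shared calendar")
  n_train <- max(1, floor(train_frac * length(shared)))
  tr <- seq_len(n_train)
  va <- setdiff(seq_along(shared), tr)

  src <- tibble(source_id = rownames(sm))
  src$lon <- sources$lon[match(src$source_id, sources[[id_col]])]
  src$lat <- sources$lat[match(src$source_id, sources[[id_col]])]

  fit_one <- function(i) {
    ref_tr <- rm_[i, tr]
    ref_va <- rm_[i, va]
    obj <- function(p) {
      dist <- haversine_km(p[1], p[2], src$lon, src$lat)
      w <- softmax_neg(softplus(p[4]) * dist)
      pred <- as.vector(w %*% sm[, tr, drop = FALSE]) + p[3]
      mean((pred - ref_tr)^2)
    }
    j <- match(rownames(rm_)[i], districts$district_id)
    p0 <- c(districts$lon[j], districts$lat[j], 0, softplus_inv(1))
    fit <- optim(p0, obj, method = "L-BFGS-B", control = list(maxit = maxit))
    dist <- haversine_km(fit$par[1], fit$par[2], src$lon, src$lat)
    w <- softmax_neg(softplus(fit$par[4]) * dist)
    pred_va <- if (length(va)) as.vector(w %*% sm[, va, drop = FALSE]) + fit$par[3] else numeric(0)
    list(par = fit$par,
         train_rmse = sqrt(fit$value),
         val_rmse = if (length(va)) sqrt(mean((pred_va - ref_va)^2)) else NA_real_)
  }

  fits <- map(seq_len(nrow(rm_)), fit_one)
  pars <- do.call(rbind, map(fits, "par"))
  fitted <- temp_interpolator(
    tibble(district_id = rownames(rm_), lon = pars[, 1], lat = pars[, 2],
           bias = pars[, 3], alpha = softplus(pars[, 4])),
    src
  )
  fitted$source_id_col <- id_col
  fitted$fit_report <- list(
    by_district = tibble(district_id = rownames(rm_),
                         train_rmse_c = map_dbl(fits, "train_rmse"),
                         val_rmse_c = map_dbl(fits, "val_rmse")),
    train_rmse_c = sqrt(mean(map_dbl(fits, "train_rmse")^2)),
    val_rmse_c = sqrt(mean(map_dbl(fits, "val_rmse")^2)),
    n_train_days = n_train, n_val_days = length(va)
  )
  fitted
}

#' Apply a fitted interpolator to one climate-ensemble member
#'
#' Identical mechanics to [predict_district_temperatures()]; the member must
#' be on the same grid the interpolator was fitted on, and no bias correction
#' is applied.
#'
#' @param params A fitted `temp_interpolator` whose sources are the projection
#'   grid points.
#' @param member_temps Long tibble (`point_id`, `date`, `tmean_c`) of one
#'   ensemble member.
#' @return Tibble `district_id`, `date`, `tmean_c`.
#' @export
downscale_climate_member <- function(params, member_temps) {
  id_col <- intersect(c(params$source_id_col, "source_id"), names(member_temps))[1]
  assert_that(!is.na(id_col), "member_temps must carry the grid point id column")
  got <- unique(member_temps[[id_col]])
  assert_that(setequal(got, params$sources$source_id),
              "member grid does not match the grid the interpolator was fitted on")
  predict_district_temperatures(params, member_temps)
}

#' Fill gaps in station series from a secondary gridded source
#'
#' Missing station values are substituted by the matched secondary series
#' after subtracting the mean difference (secondary minus station) over the
#' overlapping, jointly observed period.
#'
#' @param station_temps Long tibble `station_id`, `date`, `tmean_c`, possibly
#'   with `NA` values.
#' @param secondary_temps Long tibble `station_id`, `date`, `tmean_c` of the
#'   secondary source evaluated at the station locations (complete).
#' @return `station_temps` with gaps filled and a logical `filled` column.
#' @export
fill_station_gaps <- function(station_temps, secondary_temps) {
  joined <- station_temps |>
    left_join(secondary_temps |> rename(secondary_c = "tmean_c"),
              by = c("station_id", "date"))
  adj <- joined |>
    filter(!is.na(.data$tmean_c) & !is.na(.data$secondary_c)) |>
    group_by(.data$station_id) |>
    summarise(mean_diff = mean(.data$secondary_c - .data$tmean_c), .groups = "drop")
  joined <- joined |> left_join(adj, by = "station_id")
  gap <- is.na(joined$tmean_c)
  assert_that(all(!gap | !is.na(joined$secondary_c)),
              "secondary source does not cover all gaps")
  assert_that(all(!gap | !is.na(joined$mean_diff)),
              "no overlap to estimate the mean difference for some stations")
  joined$tmean_c[gap] <- joined$secondary_c[gap] - joined$mean_diff[gap]
  joined |>
    mutate(filled = gap) |>
    select("station_id", "date", "tmean_c", "filled")
}

#' @export
print.temp_interpolator <- function(x, ...) {
  cat(sprintf("<temp_interpolator> %d districts <- %d source points\n",
              nrow(x$districts), nrow(x$sources)))
  if (!is.null(x$fit_report)) {
    cat(sprintf("  fitted: train RMSE %.3f C, validation RMSE %.3f C\n",
                x$fit_report$train_rmse_c, x$fit_report$val_rmse_c))
  }
  invisible(x)
}

#' @rdname tidy.temp_interpolator
#' @export
tidy.temp_interpolator <- function(x, ...) {
  out <- x$districts
  if (!is.null(x$fit_report)) {
    out <- out |> left_join(x$fit_report$by_district, by = "district_id")
  }
  out
}

#' Tidy / glance methods for fitted interpolators
#'
#' `tidy()` returns one row per district (position, bias, alpha and, when
#' fitted, per-district RMSE); `glance()` returns one-row overall fit quality.
#'
#' @param x A `temp_interpolator`.
#' @param ... Unused.
#' @name tidy.temp_interpolator
#' @export
glance.temp_interpolator <- function(x, ...) {
  if (is.null(x$fit_report)) {
    return(tibble(n_districts = nrow(x$districts), n_sources = nrow(x$sources)))
  }
  tibble(
    n_districts = nrow(x$districts), n_sources = nrow(x$sources),
    train_rmse_c = x$fit_report$train_rmse_c,
    val_rmse_c = x$fit_report$val_rmse_c,
    n_train_days = x$fit_report$n_train_days,
    n_val_days = x$fit_report$n_val_days
  )
}
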