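# Readers and writers for the standard on-disk formats. Tables travel as CSV
# (always) or Parquet (when the arrow package is available); district
# geometry as GeoJSON points; every artifact written by write_table() gets a
# JSON metadata sidecar carrying the config hash, seed and package version.

#' Read and validate a station observation table
#'
#' Expects a CSV with columns `station_id`, `lon`, `lat`, `date`, `tmean_c`.
#' Duplicate `(station_id, date)` rows are an error (naming the first
#' offender); missing values and calendar gaps are flagged, not filled.
#'
#' @param path CSV file path.
#' @return Tibble `station_id`, `lon`, `lat`, `date`, `tmean_c` with
#'   attributes `gap_report` (tibble `station_id`, `date` of missing calendar
#'   days per station, relative to the table's overall date range) and
#'   `stations` (distinct station positions).
#' @export
read_station_table <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           station_id = readr::col_character(),
                           lon = readr::col_double(),
                           lat = readr::col_double(),
                           date = readr::col_date(),
                           tmean_c = readr::col_double()
                         ))
  needed <- c("station_id", "lon", "lat", "date", "tmean_c")
  miss <- setdiff(needed, names(tbl))
  assert_that(length(miss) == 0,
              sprintf("missing mandatory column(s): %s", paste(miss, collapse = ", ")))
  dup <- tbl |> count(.data$station_id, .data$date) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate (station_id, date) rows, first: %s on %s",
                  dup$station_id[1], dup$date[1]))
  }
  cal <- seq(min(tbl$date), max(tbl$date), by = "day")
  gaps <- tbl |>
    distinct(.data$station_id) |>
    crossing(date = cal) |>
    anti_join(tbl |> filter(!is.na(.data$tmean_c)),
              by = c("station_id", "date"))
  attr(tbl, "gap_report") <- gaps
  attr(tbl, "stations") <- tbl |> distinct(.data$station_id, .data$lon, .data$lat)
  tbl
}

#' Write a table as CSV (and Parquet) with a metadata sidecar
#'
#' @param tbl A data frame.
#' @param path Output path ending in `.csv`; a `.parquet` twin is written when
#'   the arrow package is installed, and a `.meta.json` sidecar always.
#' @param config_hash,seed Provenance recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_table <- function(tbl, path, config_hash = NA_character_, seed = NA_integer_) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tbl, path)
  if (requireNamespace("arrow", quietly = TRUE)) {
    arrow::write_parquet(tbl, sub("\\.csv$", ".parquet", path))
  }
  meta <- list(
    config_hash = config_hash, seed = seed,
    version = as.character(utils::packageVersion("heatmort")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    rows = nrow(tbl), columns = names(tbl)
  )
  jsonlite::write_json(meta, paste0(sub("\\.csv$", "", path), ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write district reference points as GeoJSON
#'
#' @param districts Tibble `district_id`, `state_id`, `lon`, `lat` plus any
#'   extra property columns.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_district_geojson <- function(districts, path) {
  props <- setdiff(names(districts), c("lon", "lat"))
  features <- lapply(seq_len(nrow(districts)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(districts$lon[i], districts$lat[i])),
      properties = as.list(districts[i, props, drop = FALSE])
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialise a fitted exposure ensemble to JSON
#'
#' A plain-text checkpoint: every instance's response-function weights,
#' baseline and day-of-week factors, plus the training configuration.
#' [read_exposure_fit()] restores an equivalent `exposure_fit`.
#'
#' @param fit An `exposure_fit`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_exposure_fit <- function(fit, path) {
  ser <- list(
    config = unclass(fit$config),
    ref_date = as.character(fit$ref_date),
    groups = fit$groups,
    districts = fit$districts,
    population = fit$population,
    fit_report = fit$fit_report,
    instances = lapply(fit$instances, function(inst) {
      list(
        seed = inst$seed,
        dow_factors = inst$dow_factors,
        baseline = inst$baseline,
        response = lapply(inst$response, function(p) {
          list(variant = p$variant, inner_weights = p$inner_weights,
               inner_bias = p$inner_bias, mix_weights = p$mix_weights,
               mix_bias = p$mix_bias)
        })
      )
    })
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_exposure_fit
#' @param path Path of a checkpoint written by [write_exposure_fit()].
#' @export
read_exposure_fit <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) unlist(x, use.names = FALSE)
  cfg <- ser$config
  config <- train_config(
    train_years = num(cfg$train_years),
    validation_years = num(cfg$validation_years),
    ensemble_size = cfg$ensemble_size, seeds = num(cfg$seeds),
    variant = cfg$variant, l = cfg$l, d = cfg$d, lr = cfg$lr,
    epochs = cfg$epochs, patience = cfg$patience,
    use_dow = isTRUE(cfg$use_dow),
    streams_enabled = num(cfg$streams_enabled),
    metric_exclusion_years = num(cfg$metric_exclusion_years) %||% integer(0)
  )
  groups <- num(ser$groups)
  # data frames serialise as arrays of row-objects
  list_tbl <- function(x) bind_rows(lapply(x, as_tibble))
  instances <- lapply(ser$instances, function(inst) {
    response <- setNames(lapply(groups, function(g) {
      p <- inst$response[[g]]
      d <- length(p$inner_bias)
      exposure_params(p$variant,
                      matrix(num(p$inner_weights), nrow = d, byrow = TRUE),
                      num(p$inner_bias), num(p$mix_weights), p$mix_bias)
    }), groups)
    list(response = response, baseline = list_tbl(inst$baseline),
         dow_factors = num(inst$dow_factors), seed = inst$seed)
  })
  structure(
    list(instances = instances, config = config,
         districts = list_tbl(ser$districts),
         population = list_tbl(ser$population),
         ref_date = as.Date(ser$ref_date), groups = groups,
         fit_report = list_tbl(ser$fit_report)),
    class = "exposure_fit"
  )
}
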