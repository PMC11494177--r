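# Pipeline configuration: a single YAML document with one section per stage.
# Unknown keys are rejected (typos surface immediately); defaults fill
# everything else; a content hash of the resolved configuration is embedded
# in the metadata of every artifact written by the writers.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "output",
    log_level = "info",
    region = list(
      n_states = 4L, n_districts = 20L, n_stations = 30L,
      bbox = c(6, 15, 47, 55), urban_fraction = 0.25,
      heat_island_amplitude = 2, years = 2011:2020, old_age_share = 0.12
    ),
    interpolator = list(train_frac = 0.8, maxit = 200L),
    train = list(
      train_years = 2011:2018, validation_years = 2019:2020,
      ensemble_size = 20L, variant = "exponential", l = 7L, d = 8L,
      lr = 0.05, epochs = 2000L, patience = 50L, use_dow = TRUE,
      metric_exclusion_years = integer(0)
    ),
    attribution = list(cap_c = 20, per_million = TRUE, top_k = 10L),
    projection = list(n_members = 50L, freeze_year = NULL,
                      population_mode = "static")
  )
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_nulls)
}

merge_config <- function(defaults, user, path = character(0)) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(paste(c(path, unknown[1]), collapse = "."),
                        collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      assert_that(is.list(user[[k]]),
                  sprintf("key '%s' must be a mapping",
                          paste(c(path, k), collapse = ".")))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML document, rejects unknown keys (naming the offender), fills
#' defaults (cap 20 C, ensemble size 20, lag 7, 2011-2018 / 2019-2020 split),
#' validates cross-field consistency and attaches a content hash.
#'
#' @param path Path to a YAML file, or `NULL` for an all-default config.
#' @return Object of class `pipeline_config`: the nested configuration list
#'   with a `config_hash` field.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) {
    list()
  } else {
    assert_that(file.exists(path), sprintf("config file not found: %s", path))
    yaml::read_yaml(path) %||% list()
  }
  cfg <- merge_config(pipeline_defaults(), user)
  assert_that(cfg$train$ensemble_size >= 1, "train.ensemble_size must be >= 1")
  assert_that(cfg$train$l >= 1, "train.l must be >= 1")
  assert_that(cfg$attribution$cap_c > -100 && is.finite(cfg$attribution$cap_c),
              "attribution.cap_c must be finite")
  assert_that(cfg$attribution$top_k >= 1, "attribution.top_k must be >= 1")
  assert_that(length(intersect(cfg$train$train_years,
                               cfg$train$validation_years)) == 0,
              "train and validation years overlap")
  assert_that(cfg$region$n_districts >= cfg$region$n_states,
              "region.n_districts must be >= region.n_states")
  cfg$config_hash <- config_hash(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Content hash of a configuration
#'
#' MD5 of the canonical JSON serialisation (hash field excluded), so
#' serialise-and-reload round-trips to the identical hash.
#'
#' @param cfg A configuration list.
#' @return Character scalar (32 hex digits).
#' @export
config_hash <- function(cfg) {
  cfg$config_hash <- NULL
  cfg <- drop_nulls(unclass(cfg)) # NULL-valued keys don't survive YAML round-trips
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

#' Serialise a pipeline configuration back to YAML
#'
#' @param cfg A `pipeline_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$config_hash <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> seed %d, hash %s\n", x$seed,
              substr(x$config_hash, 1, 8)))
  cat(sprintf("  region: %d districts / %d states, years %d-%d\n",
              x$region$n_districts, x$region$n_states,
              min(x$region$years), max(x$region$years)))
  cat(sprintf("  train: %s, ensemble %d, l = %d, d = %d; cap %.0f C\n",
              x$train$variant, x$train$ensemble_size, x$train$l, x$train$d,
              x$attribution$cap_c))
  invisible(x)
}
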