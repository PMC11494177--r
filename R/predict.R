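# Prediction from a fitted ensemble, and the elementary expected-deaths
# arithmetic shared by simulator and model:
#   E = baseline(t) x population(t) x f(T lag vector) x dow(weekday).

#' Expected deaths from baseline, population, response factors and day-of-week
#'
#' Elementary arithmetic of the mortality model on tidy inputs. `factors` is
#' joined onto the population table by whatever key columns it shares with it
#' (`district_id`, `date`, `sex`, ...), so a single factor column can apply to
#' all strata of a district-day or be stratum-specific.
#'
#' @param population_daily Tibble `date`, `district_id`, `sex`, `age_band`,
#'   `pop` (e.g. from [interpolate_population_daily()]).
#' @param baseline Baseline tibble `sex`, `age_band`, `log_daily_rate0`,
#'   `trend_per_year` (see [baseline_spec()]).
#' @param factors Tibble with a `factor` column and any subset of the
#'   population key columns to join on; defaults to `factor = 1` everywhere.
#' @param dow_factors Seven multiplicative day-of-week factors (Monday first),
#'   mean 1; default all 1.
#' @param ref_date Date at which `log_daily_rate0` applies; defaults to the
#'   earliest date in `population_daily`.
#' @return `population_daily` with an `expected` column.
#' @export
expected_deaths <- function(population_daily, baseline, factors = NULL,
                            dow_factors = rep(1, 7), ref_date = NULL) {
  assert_that(length(dow_factors) == 7, "dow_factors must have length 7")
  ref_date <- ref_date %||% min(population_daily$date)
  out <- population_daily |>
    left_join(baseline, by = c("sex", "age_band"))
  assert_that(!anyNA(out$log_daily_rate0),
              "baseline does not cover all strata in population_daily")
  if (is.null(factors)) {
    out$factor <- 1
  } else {
    keys <- intersect(setdiff(names(factors), "factor"), names(out))
    assert_that(length(keys) > 0, "factors shares no key columns with population")
    out <- out |> left_join(factors, by = keys)
    assert_that(!anyNA(out$factor), "factors do not cover all strata")
  }
  tau <- as.numeric(out$date - ref_date) / 365.25
  out$expected <- exp(out$log_daily_rate0 + out$trend_per_year * tau) *
    out$pop * out$factor * dow_factors[weekday_index(out$date)]
  out |> select(-"log_daily_rate0", -"trend_per_year", -"factor")
}

# ---- ensemble prediction engine -------------------------------------------

# Per-instance daily expected deaths, by (group, district, day).
# Returns list(Dg = list of 8 nd x nt matrices, total = nd x nt).
inst_daily_expected <- function(inst, L, P, dates, ref_date,
                                dow_correct = TRUE, baseline_freeze_date = NULL,
                                group_of, nd) {
  nt <- length(dates)
  st <- stratum_table()
  tau <- if (is.null(baseline_freeze_date)) {
    as.numeric(dates - ref_date) / 365.25
  } else {
    rep(as.numeric(as.Date(baseline_freeze_date) - ref_date) / 365.25, nt)
  }
  bl <- inst$baseline
  bidx <- match(st$stratum, paste(bl$sex, bl$age_band, sep = ":"))
  B <- exp(outer(bl$log_daily_rate0[bidx], rep(1, nt)) +
             outer(bl$trend_per_year[bidx], tau))
  w_dow <- if (dow_correct) inst$dow_factors[weekday_index(dates)] else rep(1, nt)

  groups <- names(inst$response)
  Q <- lapply(seq_along(groups), function(g) matrix(0, nrow = nd, ncol = nt))
  for (s in seq_len(nrow(st))) {
    g <- group_of[s]
    Ps <- P[s, , , drop = TRUE]
    if (nd == 1) Ps <- matrix(Ps, nrow = 1)
    Q[[g]] <- Q[[g]] + Ps * rep(B[s, ], each = nd)
  }
  Dg <- lapply(seq_along(groups), function(g) {
    f <- response_factor(inst$response[[g]], L)
    matrix(f, nrow = nd) * Q[[g]] * rep(w_dow, each = nd)
  })
  names(Dg) <- groups
  list(Dg = Dg, total = Reduce(`+`, Dg))
}

prediction_inputs <- function(fit, temps, population) {
  tm <- series_matrix(temps, "district_id")
  dates <- attr(tm, "dates")
  assert_that(all(diff(as.integer(dates)) == 1), "temps calendar has gaps")
  list(
    tm = tm, dates = dates, district_ids = rownames(tm),
    L = lag_matrix_from_mat(tm, fit$config$l),
    P = suppressWarnings(pop_array(population, dates, rownames(tm))),
    group_of = match(stratum_table()$group, fit$groups)
  )
}

#' Predict daily expected deaths from a fitted ensemble
#'
#' Runs every requested instance of the ensemble forward on a district
#' temperature table and averages the instance-level daily expected deaths
#' (the ensemble's final predictor).
#'
#' @param fit An [train_ensemble()] result.
#' @param temps Tibble `district_id`, `date`, `tmean_c`, contiguous daily
#'   calendar.
#' @param population Annual population snapshots (`district_id`, `sex`,
#'   `age_band`, `year`, `pop`); defaults to the snapshots used for fitting.
#' @param level Output resolution: `"district_day"` (default),
#'   `"national_day"`, or `"group_day"` (sex x broad age by district-day).
#' @param instances `"mean"` (ensemble average, default) or `"all"` (one row
#'   set per instance, with an `instance` column).
#' @param dow_correct Apply the fitted day-of-week factors?
#' @param baseline_freeze_date Optional date; when set, baseline rates are
#'   pinned to this date for the whole prediction period (e.g. for periods
#'   where no reliable contemporary baseline exists).
#' @return Tibble with an `expected` column at the requested resolution.
#' @export
predict_expected_deaths <- function(fit, temps, population = fit$population,
                                    level = c("district_day", "national_day",
                                              "group_day"),
                                    instances = c("mean", "all"),
                                    dow_correct = TRUE,
                                    baseline_freeze_date = NULL) {
  level <- match.arg(level)
  instances <- match.arg(instances)
  pin <- prediction_inputs(fit, temps, population)
  nd <- length(pin$district_ids)

  one <- function(inst) {
    inst_daily_expected(inst, pin$L, pin$P, pin$dates, fit$ref_date,
                        dow_correct, baseline_freeze_date, pin$group_of, nd)
  }
  shape <- function(res) {
    if (level == "district_day") {
      tibble(date = rep(pin$dates, each = nd),
             district_id = rep(pin$district_ids, times = length(pin$dates)),
             expected = as.vector(res$total))
    } else if (level == "national_day") {
      tibble(date = pin$dates, expected = unname(colSums(res$total)))
    } else {
      bind_rows(imap(res$Dg, function(m, grp) {
        parts <- strsplit(grp, ":", fixed = TRUE)[[1]]
        tibble(date = rep(pin$dates, each = nd),
               district_id = rep(pin$district_ids, times = length(pin$dates)),
               sex = parts[1], age_band = parts[2],
               expected = as.vector(m))
      }))
    }
  }

  if (instances == "mean") {
    res <- one(fit$instances[[1]])
    if (length(fit$instances) > 1) {
      for (inst in fit$instances[-1]) {
        r2 <- one(inst)
        res$total <- res$total + r2$total
        res$Dg <- map2(res$Dg, r2$Dg, `+`)
      }
      res$total <- res$total / length(fit$instances)
      res$Dg <- map(res$Dg, ~ .x / length(fit$instances))
    }
    shape(res)
  } else {
    bind_rows(imap(fit$instances, function(inst, i) {
      shape(one(inst)) |> mutate(instance = i)
    }))
  }
}

#' Population-weighted national mean temperature
#'
#' @param temps Tibble `district_id`, `date`, `tmean_c`.
#' @param population Annual snapshots; district weights are total population
#'   in the earliest snapshot year.
#' @return Tibble `date`, `tmean_c`.
#' @export
national_mean_temperature <- function(temps, population) {
  w <- population |>
    filter(.data$year == min(.data$year)) |>
    group_by(.data$district_id) |>
    summarise(w = sum(.data$pop), .groups = "drop")
  temps |>
    left_join(w, by = "district_id") |>
    group_by(.data$date) |>
    summarise(tmean_c = sum(.data$tmean_c * .data$w) / sum(.data$w),
              .groups = "drop")
}
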