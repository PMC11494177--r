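# Reporting streams: the three aggregation levels at which mortality is
# released by the statistics office, all exact sums of the daily
# district-level records. Weekly streams use ISO-8601 weeks; partial weeks at
# the edges of the covered calendar are dropped so that every weekly cell is
# an exact 7-day sum.

#' Aggregate a daily stratified series to a reporting stream
#'
#' @param daily Tibble with columns `date`, `district_id`, `sex`, `age_band`
#'   (5-year bands) and a value column.
#' @param stream One of `"daily_state_sex"`, `"weekly_state_sex_broad"`,
#'   `"weekly_national_sex_fine"`.
#' @param districts Tibble mapping `district_id` to `state_id` (e.g.
#'   `region$districts`); not needed for the national stream.
#' @param value_col Name of the value column to sum (default `"deaths"`).
#' @return A tibble at the stream's resolution with the summed value column:
#'   daily stream: `date`, `state_id`, `sex`; weekly state stream: `iso_week`,
#'   `state_id`, `sex`, `age_band` (broad); weekly national stream:
#'   `iso_week`, `sex`, `age_band` (fine).
#' @export
aggregate_to_stream <- function(daily,
                                stream = c("daily_state_sex",
                                           "weekly_state_sex_broad",
                                           "weekly_national_sex_fine"),
                                districts = NULL,
                                value_col = "deaths") {
  stream <- match.arg(stream)
  assert_that(value_col %in% names(daily),
              sprintf("column '%s' not found in daily table", value_col))
  v <- rlang::sym(value_col)

  if (stream != "weekly_national_sex_fine") {
    assert_that(!is.null(districts) && all(c("district_id", "state_id") %in% names(districts)),
                "districts with state_id mapping required for state-level streams")
    daily <- daily |>
      left_join(districts |> select("district_id", "state_id"), by = "district_id")
    assert_that(!anyNA(daily$state_id), "some districts have no state mapping")
  }

  if (stream == "daily_state_sex") {
    return(daily |>
             group_by(.data$date, .data$state_id, .data$sex) |>
             summarise(!!v := sum(!!v), .groups = "drop"))
  }

  daily$iso_week <- iso_week_key(daily$date)
  full_weeks <- complete_iso_weeks(daily$date)
  daily <- daily |> filter(.data$iso_week %in% full_weeks)

  if (stream == "weekly_state_sex_broad") {
    daily |>
      mutate(age_band = age_band_to(.data$age_band, "broad")) |>
      group_by(.data$iso_week, .data$state_id, .data$sex, .data$age_band) |>
      summarise(!!v := sum(!!v), .groups = "drop")
  } else {
    daily |>
      mutate(age_band = age_band_to(.data$age_band, "fine")) |>
      group_by(.data$iso_week, .data$sex, .data$age_band) |>
      summarise(!!v := sum(!!v), .groups = "drop")
  }
}

# ISO weeks fully contained in the calendar span of `dates`
complete_iso_weeks <- function(dates) {
  cal <- seq(min(dates), max(dates), by = "day")
  wk <- iso_week_key(cal)
  keep <- table(wk)
  names(keep)[keep == 7]
}

#' Build the three mortality reporting tables from simulated deaths
#'
#' Emits the three aggregation streams released by the statistics office:
#' (1) daily x state x sex; (2) ISO-weekly x state x sex x broad age bands
#' (0-65, 65-75, 75-85, 85+); (3) ISO-weekly x national x sex x fine age bands
#' (0-30, 5-year bands to 90-95, 95+). Each cell is an exact sum of the daily
#' district records; partial ISO weeks at the calendar edges are dropped from
#' the weekly streams.
#'
#' @param truth A [generate_mortality_counts()] result, or a daily tibble with
#'   columns `date`, `district_id`, `sex`, `age_band`, `deaths`.
#' @param districts District-to-state mapping; defaults to the truth's region.
#' @return Named list of tibbles `daily_state_sex`, `weekly_state_sex_broad`,
#'   `weekly_national_sex_fine`.
#' @export
build_reporting_tables <- function(truth, districts = NULL) {
  if (inherits(truth, "synthetic_truth")) {
    daily <- truth$deaths
    districts <- districts %||% truth$region$districts
  } else {
    daily <- truth
  }
  list(
    daily_state_sex =
      aggregate_to_stream(daily, "daily_state_sex", districts),
    weekly_state_sex_broad =
      aggregate_to_stream(daily, "weekly_state_sex_broad", districts),
    weekly_national_sex_fine =
      aggregate_to_stream(daily, "weekly_national_sex_fine")
  )
}
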