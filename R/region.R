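#' Generate the synthetic study region and its population
#'
#' Lays out states and districts inside the bounding box, flags urban districts
#' with a constant heat-island offset, places weather stations, and produces
#' annual December-31 population snapshots per district, sex and 5-year age
#' band. The age pyramid is parametric and calibrated so the national share of
#' the population aged 75+ matches `config$old_age_share`; district totals are
#' log-normal around 180,000 inhabitants and drift log-linearly over the years.
#'
#' @param config A [region_config()].
#' @return A list of class `synthetic_region` with elements
#'   \describe{
#'     \item{districts}{tibble: `district_id`, `state_id`, `lon`, `lat`,
#'       `urban`, `heat_island_c`.}
#'     \item{stations}{tibble: `station_id`, `lon`, `lat`.}
#'     \item{population}{tibble: `district_id`, `sex` (`"f"`/`"m"`),
#'       `age_band` (5-year), `year`, `pop` — population on 31 December; the
#'       year before the simulation start is included so daily interpolation
#'       covers the whole period.}
#'     \item{config}{the input configuration.}
#'   }
#' @examples
#' region <- generate_region(region_config(n_districts = 6, n_states = 2))
#' dplyr::count(region$districts, state_id)
#' @export
generate_region <- function(config) {
  validate_region_config(config)
  with_seed(child_seed(config$seed, 1), {
    nd <- config$n_districts
    ns <- config$n_states
    bbox <- config$bbox

    # state centres, then districts jittered around their parent state centre
    state_ids <- sprintf("S%02d", seq_len(ns))
    centres <- tibble(
      state_id = state_ids,
      lon = runif(ns, bbox[1] + 0.1 * diff(bbox[1:2]), bbox[2] - 0.1 * diff(bbox[1:2])),
      lat = runif(ns, bbox[3] + 0.1 * diff(bbox[3:4]), bbox[4] - 0.1 * diff(bbox[3:4]))
    )
    # every state gets one district, remainder assigned at random
    assignment <- c(seq_len(ns), sample(ns, nd - ns, replace = TRUE))
    spread_lon <- 0.18 * diff(bbox[1:2])
    spread_lat <- 0.18 * diff(bbox[3:4])
    districts <- tibble(
      district_id = sprintf("D%03d", seq_len(nd)),
      state_id = state_ids[assignment],
      lon = pmin(pmax(centres$lon[assignment] + rnorm(nd, 0, spread_lon), bbox[1]), bbox[2]),
      lat = pmin(pmax(centres$lat[assignment] + rnorm(nd, 0, spread_lat), bbox[3]), bbox[4])
    )
    n_urban <- round(config$urban_fraction * nd)
    urban_idx <- if (n_urban > 0) sample(nd, n_urban) else integer(0)
    districts$urban <- seq_len(nd) %in% urban_idx
    districts$heat_island_c <- 0
    if (n_urban > 0) {
      districts$heat_island_c[urban_idx] <-
        runif(n_urban, 0.3, 1) * config$heat_island_amplitude
    }

    stations <- tibble(
      station_id = sprintf("ST%03d", seq_len(config$n_stations)),
      lon = runif(config$n_stations, bbox[1], bbox[2]),
      lat = runif(config$n_stations, bbox[3], bbox[4])
    )

    population <- generate_population_snapshots(districts, config)

    structure(
      list(districts = districts, stations = stations,
           population = population, config = config),
      class = "synthetic_region"
    )
  })
}

# Parametric age pyramid over the 20 five-year bands: a plateau through the
# working ages with geometric decay above 70, rescaled so the 75+ share hits
# the configured target exactly at the national level.
pyramid_weights <- function(old_age_share) {
  bands <- age_bands_5yr()
  mid <- band_midpoint(bands)
  w <- ifelse(mid < 70, 1 - 0.004 * mid, 0.72 * 0.55^((mid - 70) / 5))
  old <- band_lower(bands) >= 75
  w_old <- w[old] / sum(w[old]) * old_age_share
  w_yng <- w[!old] / sum(w[!old]) * (1 - old_age_share)
  w[old] <- w_old
  w[!old] <- w_yng
  setNames(w, bands)
}

generate_population_snapshots <- function(districts, config) {
  bands <- age_bands_5yr()
  w <- pyramid_weights(config$old_age_share)
  nd <- nrow(districts)
  totals0 <- rlnorm(nd, meanlog = log(180000), sdlog = 0.45)
  growth <- rnorm(nd, 0.002, 0.003) # annual log-growth per district
  # female share rises with age (elderly cohorts skew female)
  f_share <- pmin(0.49 + 0.0016 * band_midpoint(bands), 0.68)
  # small per-district pyramid jitter, renormalised so shares stay near target
  jitter <- matrix(rlnorm(nd * length(bands), 0, 0.05), nrow = nd)
  wd <- sweep(jitter, 2, w, `*`)
  wd <- wd / rowSums(wd)

  grid <- expand_grid(
    d = seq_len(nd),
    year = c(min(config$years) - 1L, config$years),
    b = seq_along(bands),
    sex = c("f", "m")
  )
  pop <- totals0[grid$d] * exp(growth[grid$d] * (grid$year - min(config$years))) *
    wd[cbind(grid$d, grid$b)] *
    ifelse(grid$sex == "f", f_share[grid$b], 1 - f_share[grid$b])
  tibble(
    district_id = districts$district_id[grid$d],
    sex = grid$sex,
    age_band = bands[grid$b],
    year = grid$year,
    pop = pop
  ) |>
    arrange(.data$district_id, .data$sex, .data$year)
}

#' @export
print.synthetic_region <- function(x, ...) {
  cat(sprintf("<synthetic_region> %d districts in %d states, %d stations\n",
              nrow(x$districts), length(unique(x$districts$state_id)),
              nrow(x$stations)))
  cat(sprintf("  population %.2fM (%d-%d), urban districts: %d\n",
              sum(x$population$pop[x$population$year == min(x$config$years)]) / 1e6,
              min(x$config$years), max(x$config$years), sum(x$districts$urban)))
  invisible(x)
}
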