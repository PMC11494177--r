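# Calibration of the exposure-response model against the aggregated
# reporting streams. The daily, district-, sex- and 5-year-age-specific
# expectation
#
#   E = baseline_{sex,age}(t) * population_{district,sex,age}(t)
#       * f_{sex,broad-age}(T lag vector) * dow(weekday)
#
# is summed to the resolution of each enabled stream and scored with the
# Poisson negative log-likelihood. One response function is shared per
# (sex x broad age) group — the finest stratification jointly identifiable
# from the weekly state (broad-age) and weekly national (fine-age) streams.
# Training is full-batch Adam on analytic gradients with an epoch cap and
# early stopping on validation NLL; an ensemble of independently initialised
# instances is averaged to reduce initialisation variance.

#' Training configuration for the exposure-response ensemble
#'
#' @param train_years,validation_years Disjoint calendar-year sets (80:20
#'   temporal split by default when the data cover ten years).
#' @param ensemble_size Number of independently initialised instances whose
#'   averaged output is the final predictor (default 20).
#' @param seeds Optional integer vector, one seed per instance; derived from
#'   `seed` when `NULL`.
#' @param seed Master seed used to derive per-instance seeds.
#' @param variant Exposure-response variant, `"exponential"` (default) or
#'   `"linear"`.
#' @param l Lag window length in days (lag vectors have `l + 1` entries).
#' @param d Hidden dimension (number of exponential / rectified terms).
#' @param lr Adam learning rate.
#' @param epochs Epoch cap.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param use_dow Fit multiplicative day-of-week factors (mean constrained to
#'   exactly 1)?
#' @param streams_enabled Which reporting streams enter the pooled loss.
#' @param metric_exclusion_years Years excluded from metric evaluation (not
#'   from training).
#' @return Object of class `train_config`.
#' @export
train_config <- function(train_years = 2011:2018,
                         validation_years = 2019:2020,
                         ensemble_size = 20,
                         seeds = NULL,
                         seed = 1L,
                         variant = c("exponential", "linear"),
                         l = 7, d = 8,
                         lr = 0.05, epochs = 2000, patience = 50,
                         use_dow = TRUE,
                         streams_enabled = c("daily_state_sex",
                                             "weekly_state_sex_broad",
                                             "weekly_national_sex_fine"),
                         metric_exclusion_years = integer(0)) {
  variant <- match.arg(variant)
  assert_that(length(intersect(train_years, validation_years)) == 0,
              "train and validation years must be disjoint")
  assert_that(ensemble_size >= 1, "ensemble_size must be >= 1")
  if (is.null(seeds)) seeds <- vapply(seq_len(ensemble_size),
                                      function(i) child_seed(seed, 100 + i),
                                      integer(1))
  assert_that(length(seeds) >= ensemble_size,
              "fewer seeds than ensemble_size")
  structure(
    list(train_years = as.integer(train_years),
         validation_years = as.integer(validation_years),
         ensemble_size = as.integer(ensemble_size),
         seeds = as.integer(seeds[seq_len(ensemble_size)]),
         variant = variant, l = as.integer(l), d = as.integer(d),
         lr = lr, epochs = as.integer(epochs), patience = as.integer(patience),
         use_dow = isTRUE(use_dow), streams_enabled = streams_enabled,
         metric_exclusion_years = as.integer(metric_exclusion_years)),
    class = "train_config"
  )
}

#' Poisson negative log-likelihood (constants in the observation dropped)
#'
#' `sum(lambda - y * log(lambda))` over all cells; `lambda` is floored at
#' `1e-8` so early, badly scaled iterates survive.
#'
#' @param expected Non-negative expected counts (lambda).
#' @param observed Observed counts of the same length.
#' @return Scalar loss.
#' @examples
#' poisson_nll(1, 1) # = 1, the minimum of lambda - 1 * log(lambda)
#' @export
poisson_nll <- function(expected, observed) {
  assert_that(length(expected) == length(observed),
              "expected and observed must have equal length")
  assert_that(all(expected >= 0), "expected must be non-negative")
  lam <- pmax(expected, 1e-8)
  sum(lam - observed * log(lam))
}

# ---- fit context ----------------------------------------------------------

build_fit_context <- function(streams, temps, region, config) {
  tm <- series_matrix(temps, "district_id")
  dates <- attr(tm, "dates")
  assert_that(all(diff(as.integer(dates)) == 1), "temps calendar has gaps")
  district_ids <- rownames(tm)
  districts <- region$districts
  state_ids <- sort(unique(districts$state_id))
  st <- stratum_table()
  groups <- unique(st$group)

  years <- as.integer(format(dates, "%Y"))
  covered <- intersect(c(config$train_years, config$validation_years), years)
  assert_that(length(intersect(config$train_years, years)) > 0,
              "training years not covered by the temperature calendar")

  wk_key <- iso_week_key(dates)
  kept_weeks <- complete_iso_weeks(dates)
  week_idx <- match(wk_key, kept_weeks) # NA for partial edge weeks
  week_year <- as.integer(substr(kept_weeks, 1, 4))

  # observed stream arrays aligned to the model's cell layout
  y1 <- stream_array_daily(streams$daily_state_sex, state_ids, dates)
  y2 <- stream_array_weekly_state(streams$weekly_state_sex_broad,
                                  state_ids, kept_weeks)
  y3 <- stream_array_weekly_national(streams$weekly_national_sex_fine,
                                     kept_weeks)

  day_in <- function(yrs) years %in% yrs
  week_in <- function(yrs) week_year %in% yrs

  list(
    tm = tm, dates = dates, ref_date = dates[1],
    district_ids = district_ids, state_ids = state_ids,
    state_of_district = match(districts$state_id[match(district_ids, districts$district_id)],
                              state_ids),
    st = st, groups = groups,
    group_of_stratum = match(st$group, groups),
    L = lag_matrix_from_mat(tm, config$l) - 20, # centred at the 20 C reference
    P = pop_array(region$population, dates, district_ids),
    tau = as.numeric(dates - dates[1]) / 365.25,
    wd = weekday_index(dates),
    week_idx = week_idx, kept_weeks = kept_weeks,
    y1 = y1, y2 = y2, y3 = y3,
    mask1 = list(train = day_in(config$train_years),
                 val = day_in(config$validation_years)),
    maskw = list(train = week_in(config$train_years),
                 val = week_in(config$validation_years)),
    config = config
  )
}

stream_array_daily <- function(tbl, state_ids, dates) {
  assert_that(!is.null(tbl), "daily_state_sex stream is required")
  a <- array(NA_real_, dim = c(length(state_ids), 2, length(dates)))
  idx <- cbind(match(tbl$state_id, state_ids),
               match(tbl$sex, c("f", "m")),
               match(tbl$date, dates))
  keep <- !is.na(idx[, 3])
  a[idx[keep, , drop = FALSE]] <- tbl$deaths[keep]
  assert_that(!anyNA(a), "daily_state_sex stream incomplete on the model calendar")
  a
}

stream_array_weekly_state <- function(tbl, state_ids, kept_weeks) {
  assert_that(!is.null(tbl), "weekly_state_sex_broad stream is required")
  bands <- age_bands_broad()
  a <- array(NA_real_, dim = c(length(state_ids), 2, length(bands), length(kept_weeks)))
  idx <- cbind(match(tbl$state_id, state_ids),
               match(tbl$sex, c("f", "m")),
               match(tbl$age_band, bands),
               match(tbl$iso_week, kept_weeks))
  keep <- !is.na(idx[, 4])
  a[idx[keep, , drop = FALSE]] <- tbl$deaths[keep]
  assert_that(!anyNA(a), "weekly_state_sex_broad stream incomplete on the model calendar")
  a
}

stream_array_weekly_national <- function(tbl, kept_weeks) {
  assert_that(!is.null(tbl), "weekly_national_sex_fine stream is required")
  bands <- age_bands_fine()
  a <- array(NA_real_, dim = c(2, length(bands), length(kept_weeks)))
  idx <- cbind(match(tbl$sex, c("f", "m")),
               match(tbl$age_band, bands),
               match(tbl$iso_week, kept_weeks))
  keep <- !is.na(idx[, 3])
  a[idx[keep, , drop = FALSE]] <- tbl$deaths[keep]
  assert_that(!anyNA(a), "weekly_national_sex_fine stream incomplete on the model calendar")
  a
}

# ---- parameter packing ----------------------------------------------------

theta_layout <- function(config) {
  d <- config$d; l <- config$l
  per_group <- d * (l + 1) + d + d + 1
  n_groups <- 8L
  list(d = d, l = l, n_groups = n_groups, per_group = per_group,
       n_beta = 40L, use_dow = config$use_dow,
       total = n_groups * per_group + 2L * 40L + if (config$use_dow) 7L else 0L)
}

unpack_theta <- function(theta, lay) {
  d <- lay$d; l <- lay$l
  groups <- vector("list", lay$n_groups)
  off <- 0
  for (g in seq_len(lay$n_groups)) {
    A <- matrix(theta[off + seq_len(d * (l + 1))], nrow = d)
    off <- off + d * (l + 1)
    a0 <- theta[off + seq_len(d)]; off <- off + d
    s_raw <- theta[off + seq_len(d)]; off <- off + d
    c_raw <- theta[off + 1]; off <- off + 1
    groups[[g]] <- list(A = A, a0 = a0, s_raw = s_raw, c_raw = c_raw)
  }
  beta0 <- theta[off + seq_len(40)]; off <- off + 40
  beta1 <- theta[off + seq_len(40)]; off <- off + 40
  delta <- if (lay$use_dow) theta[off + seq_len(7)] else rep(0, 7)
  list(groups = groups, beta0 = beta0, beta1 = beta1, delta = delta)
}

pack_grad <- function(gr, lay) {
  out <- numeric(lay$total)
  off <- 0
  for (g in seq_len(lay$n_groups)) {
    gg <- gr$groups[[g]]
    n <- lay$d * (lay$l + 1)
    out[off + seq_len(n)] <- as.vector(gg$A); off <- off + n
    out[off + seq_len(lay$d)] <- gg$a0; off <- off + lay$d
    out[off + seq_len(lay$d)] <- gg$s_raw; off <- off + lay$d
    out[off + 1] <- gg$c_raw; off <- off + 1
  }
  out[off + seq_len(40)] <- gr$beta0; off <- off + 40
  out[off + seq_len(40)] <- gr$beta1; off <- off + 40
  if (lay$use_dow) out[off + seq_len(7)] <- gr$delta
  out
}

# ---- forward / backward ---------------------------------------------------

# Evaluate f for one group on a lag-row matrix given raw group params.
# During training the lag inputs are centred at 20 C (the no-heat reference),
# which decouples the inner weights from their intercepts and conditions the
# optimisation; exported parameters are converted back to the natural scale.
group_forward <- function(gp, L, variant) {
  Z <- tcrossprod(L, gp$A)
  Z <- sweep(Z, 2, gp$a0, `+`)
  if (variant == "exponential") {
    E <- exp(pmin(Z, 40)) # overflow guard far outside the data range
    s <- softplus(gp$s_raw); cc <- softplus(gp$c_raw)
    list(f = as.vector(E %*% s) + cc, E = E, Z = Z, s = s, cc = cc)
  } else {
    R <- pmax(Z, 0)
    z <- as.vector(R %*% gp$s_raw) + gp$c_raw # mixing unconstrained, softplus output
    list(f = softplus(z), E = R, Z = Z, z = z, s = gp$s_raw, cc = gp$c_raw)
  }
}

group_backward <- function(gp, fw, dF, L, variant) {
  if (variant == "exponential") {
    dc_raw <- sum(dF) * sigmoid(gp$c_raw)
    ds <- as.vector(crossprod(fw$E, dF))
    ds_raw <- ds * sigmoid(gp$s_raw)
    dZ <- fw$E * (dF %o% fw$s)
  } else {
    dz <- dF * sigmoid(fw$z)
    dc_raw <- sum(dz)
    ds_raw <- as.vector(crossprod(fw$E, dz))
    dZ <- (fw$Z > 0) * (dz %o% gp$s_raw)
  }
  list(A = crossprod(dZ, L), a0 = colSums(dZ), s_raw = ds_raw, c_raw = dc_raw)
}

# weekly aggregation of a k x n_days matrix -> k x n_weeks (full weeks only)
weekly_agg <- function(M, week_idx, n_weeks) {
  keep <- !is.na(week_idx)
  t(rowsum(t(M[, keep, drop = FALSE]), group = week_idx[keep], reorder = TRUE))
}

# scatter a k x n_weeks matrix back to the daily grid (0 on partial weeks)
weekly_scatter <- function(Mw, week_idx) {
  out <- matrix(0, nrow = nrow(Mw), ncol = length(week_idx))
  keep <- !is.na(week_idx)
  out[, keep] <- Mw[, week_idx[keep], drop = FALSE]
  out
}

# Full forward pass; returns everything backward needs.
model_forward <- function(par, ctx) {
  cfg <- ctx$config
  nd <- nrow(ctx$tm); nt <- ncol(ctx$tm); ns <- 40L
  st <- ctx$st
  fw_groups <- lapply(par$groups, group_forward, L = ctx$L, variant = cfg$variant)
  Fm <- lapply(fw_groups, function(fw) matrix(fw$f, nrow = nd)) # per group: nd x nt

  u <- exp(par$delta); w_dow <- (u / mean(u))[ctx$wd] # length nt, mean-1 factors
  B <- exp(outer(par$beta0, rep(1, nt)) + outer(par$beta1, ctx$tau)) # 40 x nt

  # Q[g]: baseline-weighted population summed over the group's strata (nd x nt)
  Q <- vector("list", 8)
  M <- matrix(0, nrow = ns, ncol = nt) # per-stratum sum_r P * F
  for (g in 1:8) Q[[g]] <- matrix(0, nrow = nd, ncol = nt)
  for (s in seq_len(ns)) {
    g <- ctx$group_of_stratum[s]
    Ps <- ctx$P[s, , , drop = TRUE]
    if (nd == 1) Ps <- matrix(Ps, nrow = 1)
    Q[[g]] <- Q[[g]] + Ps * rep(B[s, ], each = nd)
    M[s, ] <- colSums(Ps * Fm[[g]])
  }

  Dg <- lapply(1:8, function(g) Fm[[g]] * Q[[g]] * rep(w_dow, each = nd))

  # stream 1: daily x state x sex
  lam1 <- array(0, dim = dim(ctx$y1))
  for (g in 1:8) {
    sex_i <- if (startsWith(ctx$groups[g], "f")) 1 else 2
    lam1[, sex_i, ] <- lam1[, sex_i, ] +
      rowsum(Dg[[g]], group = ctx$state_of_district, reorder = TRUE)
  }

  # stream 2: weekly x state x sex x broad
  nw <- length(ctx$kept_weeks)
  lam2 <- array(0, dim = dim(ctx$y2))
  broad <- age_bands_broad()
  for (g in 1:8) {
    parts <- strsplit(ctx$groups[g], ":", fixed = TRUE)[[1]]
    sex_i <- match(parts[1], c("f", "m")); b_i <- match(parts[2], broad)
    state_mat <- rowsum(Dg[[g]], group = ctx$state_of_district, reorder = TRUE)
    lam2[, sex_i, b_i, ] <- weekly_agg(state_mat, ctx$week_idx, nw)
  }

  # stream 3: weekly x national x sex x fine — needs stratum resolution
  D3 <- B * M * rep(w_dow, each = ns) # 40 x nt national daily per stratum
  fine <- age_bands_fine()
  lam3 <- array(0, dim = dim(ctx$y3))
  fine_of <- match(st$fine_band, fine)
  sex_of <- match(st$sex, c("f", "m"))
  D3w <- weekly_agg(D3, ctx$week_idx, nw)
  for (s in seq_len(ns)) {
    lam3[sex_of[s], fine_of[s], ] <- lam3[sex_of[s], fine_of[s], ] + D3w[s, ]
  }

  list(fw_groups = fw_groups, Fm = Fm, B = B, Q = Q, M = M, Dg = Dg,
       w_dow = w_dow, u = u, lam1 = lam1, lam2 = lam2, lam3 = lam3, D3 = D3)
}

stream_losses <- function(fwd, ctx, which_mask) {
  cfg <- ctx$config
  m1 <- ctx$mask1[[which_mask]]; mw <- ctx$maskw[[which_mask]]
  loss <- 0; n_cells <- 0
  if ("daily_state_sex" %in% cfg$streams_enabled && any(m1)) {
    lam <- fwd$lam1[, , m1, drop = FALSE]; y <- ctx$y1[, , m1, drop = FALSE]
    loss <- loss + poisson_nll(lam, y); n_cells <- n_cells + length(lam)
  }
  if ("weekly_state_sex_broad" %in% cfg$streams_enabled && any(mw)) {
    lam <- fwd$lam2[, , , mw, drop = FALSE]; y <- ctx$y2[, , , mw, drop = FALSE]
    loss <- loss + poisson_nll(lam, y); n_cells <- n_cells + length(lam)
  }
  if ("weekly_national_sex_fine" %in% cfg$streams_enabled && any(mw)) {
    lam <- fwd$lam3[, , mw, drop = FALSE]; y <- ctx$y3[, , mw, drop = FALSE]
    loss <- loss + poisson_nll(lam, y); n_cells <- n_cells + length(lam)
  }
  list(loss = loss, n_cells = n_cells)
}

# d(NLL)/d(lambda) on the training cells, 0 elsewhere / when flooring is active
nll_grad_cell <- function(lam, y, mask_arr) {
  g <- array(0, dim = dim(lam))
  lamf <- pmax(lam, 1e-8)
  g[mask_arr] <- (1 - y[mask_arr] / lamf[mask_arr])
  g[lam < 1e-8] <- 0
  g
}

model_backward <- function(par, fwd, ctx, lay) {
  cfg <- ctx$config
  nd <- nrow(ctx$tm); nt <- ncol(ctx$tm); ns <- 40L
  st <- ctx$st
  m1 <- ctx$mask1$train; mw <- ctx$maskw$train

  expand1 <- function(v, dims) array(rep(v, each = prod(dims)), dim = c(dims, length(v)))
  g1 <- if ("daily_state_sex" %in% cfg$streams_enabled) {
    nll_grad_cell(fwd$lam1, ctx$y1, expand1(m1, dim(ctx$y1)[1:2]) > 0)
  } else array(0, dim = dim(ctx$y1))
  g2 <- if ("weekly_state_sex_broad" %in% cfg$streams_enabled) {
    nll_grad_cell(fwd$lam2, ctx$y2, expand1(mw, dim(ctx$y2)[1:3]) > 0)
  } else array(0, dim = dim(ctx$y2))
  g3 <- if ("weekly_national_sex_fine" %in% cfg$streams_enabled) {
    nll_grad_cell(fwd$lam3, ctx$y3, expand1(mw, dim(ctx$y3)[1:2]) > 0)
  } else array(0, dim = dim(ctx$y3))

  broad <- age_bands_broad(); fine <- age_bands_fine()
  fine_of <- match(st$fine_band, fine)
  sex_of <- match(st$sex, c("f", "m"))

  # GD[g]: nd x nt upstream gradient on Dg (streams 1 + 2)
  GD <- vector("list", 8)
  for (g in 1:8) {
    parts <- strsplit(ctx$groups[g], ":", fixed = TRUE)[[1]]
    sex_i <- match(parts[1], c("f", "m")); b_i <- match(parts[2], broad)
    per_state_daily <- g1[, sex_i, , drop = TRUE] # n_states x nt
    if (length(ctx$state_ids) == 1) per_state_daily <- matrix(per_state_daily, nrow = 1)
    gw <- g2[, sex_i, b_i, , drop = TRUE] # n_states x nw
    if (length(ctx$state_ids) == 1) gw <- matrix(gw, nrow = 1)
    per_state <- per_state_daily + weekly_scatter(gw, ctx$week_idx)
    GD[[g]] <- per_state[ctx$state_of_district, , drop = FALSE]
  }

  # GS[a, t]: upstream gradient on the national per-stratum daily D3
  GSw <- matrix(0, nrow = ns, ncol = length(ctx$kept_weeks))
  for (s in seq_len(ns)) GSw[s, ] <- g3[sex_of[s], fine_of[s], ]
  GS <- weekly_scatter(GSw, ctx$week_idx) # ns x nt

  w_rep <- rep(fwd$w_dow, each = nd)
  gr_groups <- vector("list", 8)
  dB <- matrix(0, nrow = ns, ncol = nt)
  dw <- numeric(nt)

  # R[g]: contribution of stream 3 to dF (baseline-weighted, GS-weighted pop)
  Rg <- lapply(1:8, function(g) matrix(0, nrow = nd, ncol = nt))
  GSB <- GS * fwd$B # ns x nt
  for (s in seq_len(ns)) {
    g <- ctx$group_of_stratum[s]
    Ps <- ctx$P[s, , , drop = TRUE]
    if (nd == 1) Ps <- matrix(Ps, nrow = 1)
    Rg[[g]] <- Rg[[g]] + Ps * rep(GSB[s, ], each = nd)
  }

  for (g in 1:8) {
    dFmat <- (GD[[g]] * fwd$Q[[g]] + Rg[[g]]) * matrix(w_rep, nrow = nd)
    gr_groups[[g]] <- group_backward(par$groups[[g]], fwd$fw_groups[[g]],
                                     as.vector(dFmat), ctx$L, cfg$variant)
    dw <- dw + colSums(GD[[g]] * fwd$Fm[[g]] * fwd$Q[[g]])
  }

  # baseline gradient: streams 1+2 route through Q, stream 3 through B * M
  for (s in seq_len(ns)) {
    g <- ctx$group_of_stratum[s]
    Ps <- ctx$P[s, , , drop = TRUE]
    if (nd == 1) Ps <- matrix(Ps, nrow = 1)
    dB[s, ] <- colSums(GD[[g]] * fwd$Fm[[g]] * Ps) * fwd$w_dow +
      GS[s, ] * fwd$M[s, ] * fwd$w_dow
  }
  dbeta0 <- rowSums(dB * fwd$B)
  dbeta1 <- rowSums(dB * fwd$B * rep(ctx$tau, each = ns))

  # Dg = F*Q*w  =>  dL/dw_t = sum GD*F*Q (accumulated above);
  # stream 3: D3 = B*M*w  =>  + sum GS*B*M
  dw <- dw + colSums(GS * fwd$B * fwd$M)
  ddelta <- rep(0, 7)
  if (cfg$use_dow) {
    u <- fwd$u; m <- mean(u)
    wk <- u / m
    Dw <- vapply(1:7, function(k) sum(dw[ctx$wd == k]), numeric(1))
    ddelta <- Dw * wk - (u / (7 * m)) * sum(Dw * wk)
  }

  pack_grad(list(groups = gr_groups, beta0 = dbeta0, beta1 = dbeta1,
                 delta = ddelta), lay)
}

# ---- initialisation -------------------------------------------------------

init_theta <- function(ctx, lay, seed) {
  cfg <- ctx$config
  with_seed(seed, {
    d <- lay$d; l <- lay$l
    theta <- numeric(lay$total)
    off <- 0
    for (g in seq_len(lay$n_groups)) {
      A <- matrix(rnorm(d * (l + 1), 0, 0.02), nrow = d)
      a0 <- rnorm(d, 0, 0.02) # inputs are centred, so g_k(20, ..., 20) ~ 0
      if (cfg$variant == "exponential") {
        s_raw <- rep(softplus_inv(0.5 / d), d)
        c_raw <- softplus_inv(0.5)
      } else {
        # linear variant: small unconstrained mixing, output near softplus(z0) = 1
        s_raw <- rnorm(d, 0, 0.05)
        c_raw <- softplus_inv(1)
      }
      theta[off + seq_len(d * (l + 1))] <- as.vector(A); off <- off + d * (l + 1)
      theta[off + seq_len(d)] <- a0; off <- off + d
      theta[off + seq_len(d)] <- s_raw; off <- off + d
      theta[off + 1] <- c_raw; off <- off + 1
    }
    # baseline intercepts from crude national stratum rates (f ~ 1 at init)
    crude <- crude_rates(ctx)
    theta[off + seq_len(40)] <- log(pmax(crude, 1e-10)); off <- off + 40
    theta[off + seq_len(40)] <- 0; off <- off + 40 # trend
    # delta = 0 -> dow factors 1
    theta
  })
}

# crude per-stratum daily rates from the national fine-age stream
crude_rates <- function(ctx) {
  st <- ctx$st
  fine <- age_bands_fine()
  nw <- length(ctx$kept_weeks)
  pop_nat <- apply(ctx$P, c(1, 3), sum) # 40 x nt person-days
  persondays_w <- weekly_agg(pop_nat, ctx$week_idx, nw) # 40 x nw
  rate <- numeric(40)
  for (s in seq_len(40)) {
    sex_i <- match(st$sex[s], c("f", "m"))
    f_i <- match(st$fine_band[s], fine)
    siblings <- which(st$sex == st$sex[s] & st$fine_band == st$fine_band[s])
    pd <- sum(persondays_w[siblings, ])
    rate[s] <- sum(ctx$y3[sex_i, f_i, ]) / max(pd, 1e-9)
  }
  rate
}

# ---- Adam -----------------------------------------------------------------

adam_fit <- function(theta, ctx, lay) {
  cfg <- ctx$config
  m <- numeric(length(theta)); v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(theta = theta, val = Inf, epoch = 0)
  history <- numeric(0)
  for (epoch in seq_len(cfg$epochs)) {
    fwd <- model_forward(unpack_theta(theta, lay), ctx)
    val <- stream_losses(fwd, ctx, "val")$loss
    history <- c(history, val)
    if (val < best$val - 1e-7) best <- list(theta = theta, val = val, epoch = epoch)
    if (epoch - best$epoch >= cfg$patience) break
    gr <- model_backward(unpack_theta(theta, lay), fwd, ctx, lay)
    m <- b1 * m + (1 - b1) * gr
    v <- b2 * v + (1 - b2) * gr^2
    mh <- m / (1 - b1^epoch); vh <- v / (1 - b2^epoch)
    theta <- theta - cfg$lr * mh / (sqrt(vh) + eps)
  }
  fwd_best <- model_forward(unpack_theta(best$theta, lay), ctx)
  list(theta = best$theta,
       train_nll = stream_losses(fwd_best, ctx, "train")$loss,
       val_nll = best$val, epochs_run = length(history),
       best_epoch = best$epoch, val_history = history)
}

# ---- instance -> user-facing parameter objects ----------------------------

instance_from_theta <- function(theta, lay, ctx, seed) {
  par <- unpack_theta(theta, lay)
  st <- ctx$st
  response <- setNames(lapply(seq_len(8), function(g) {
    gp <- par$groups[[g]]
    # undo the 20 C input centring: g(T) = A (T - 20) + a0 = A T + (a0 - 20 sum A)
    a0_nat <- gp$a0 - as.vector(gp$A %*% rep(20, ncol(gp$A)))
    if (ctx$config$variant == "exponential") {
      exposure_params("exponential", gp$A, a0_nat, softplus(gp$s_raw), softplus(gp$c_raw))
    } else {
      exposure_params("linear", gp$A, a0_nat, gp$s_raw, gp$c_raw)
    }
  }), ctx$groups)
  u <- exp(par$delta)
  baseline <- tibble(
    sex = st$sex, age_band = st$age_band,
    log_daily_rate0 = par$beta0, trend_per_year = par$beta1
  )
  list(response = response, baseline = baseline,
       dow_factors = u / mean(u), seed = seed)
}

#' Train an ensemble of exposure-response model instances
#'
#' Fits `config$ensemble_size` independently initialised instances by
#' minimising the pooled Poisson negative log-likelihood over the enabled
#' reporting streams on the training years (full-batch Adam with analytic
#' gradients, epoch cap and early stopping on validation NLL), and returns
#' the ensemble whose averaged daily expected deaths are the final predictor.
#'
#' @param streams Named list with the three reporting tables
#'   (`daily_state_sex`, `weekly_state_sex_broad`, `weekly_national_sex_fine`),
#'   e.g. from [build_reporting_tables()].
#' @param temps District daily mean temperatures (`district_id`, `date`,
#'   `tmean_c`), contiguous calendar.
#' @param region A [generate_region()] result (or any list with `districts`
#'   and `population` in the same layout) supplying the state mapping and
#'   annual population snapshots.
#' @param config A [train_config()].
#' @return Object of class `exposure_fit`: per-instance fitted parameters
#'   (response functions per sex x broad-age group, baseline, day-of-week
#'   factors), the fit report, and everything needed for prediction.
#' @export
train_ensemble <- function(streams, temps, region, config = train_config()) {
  assert_that(inherits(config, "train_config"), "config must be a train_config")
  ctx <- build_fit_context(streams, temps, region, config)
  lay <- theta_layout(config)
  instances <- vector("list", config$ensemble_size)
  report <- vector("list", config$ensemble_size)
  for (i in seq_len(config$ensemble_size)) {
    theta0 <- init_theta(ctx, lay, config$seeds[i])
    fit <- adam_fit(theta0, ctx, lay)
    instances[[i]] <- instance_from_theta(fit$theta, lay, ctx, config$seeds[i])
    report[[i]] <- tibble(
      instance = i, seed = config$seeds[i],
      train_nll = fit$train_nll, val_nll = fit$val_nll,
      epochs_run = fit$epochs_run, best_epoch = fit$best_epoch
    )
  }
  structure(
    list(
      instances = instances,
      config = config,
      districts = region$districts,
      population = region$population,
      ref_date = ctx$ref_date,
      groups = ctx$groups,
      fit_report = bind_rows(report)
    ),
    class = "exposure_fit"
  )
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat(sprintf("<exposure_fit> %s variant, %d instance(s), l = %d, d = %d\n",
              x$config$variant, length(x$instances), x$config$l, x$config$d))
  cat(sprintf("  mean train NLL %.1f, mean validation NLL %.1f\n",
              mean(x$fit_report$train_nll), mean(x$fit_report$val_nll)))
  invisible(x)
}

#' Tidy / glance methods for fitted exposure ensembles
#'
#' `tidy()` returns the per-instance fit report (seed, train/validation NLL,
#' epochs); `glance()` one row of ensemble-level summaries.
#'
#' @param x An `exposure_fit`.
#' @param ... Unused.
#' @export
tidy.exposure_fit <- function(x, ...) x$fit_report

#' @rdname tidy.exposure_fit
#' @export
glance.exposure_fit <- function(x, ...) {
  tibble(
    variant = x$config$variant,
    n_instances = length(x$instances),
    l = x$config$l, d = x$config$d,
    train_nll = mean(x$fit_report$train_nll),
    val_nll = mean(x$fit_report$val_nll)
  )
}
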