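test_that("response factor evaluates the exponential mixture exactly", {
  # d = 1, g_1 = 0, identity mixing, zero bias: f = exp(0) = 1
  p <- exposure_params(inner_weights = matrix(0, 1, 4), inner_bias = 0,
                       mix_weights = 1, mix_bias = 0)
  expect_equal(response_factor(p, matrix(rnorm(12), 3, 4)), rep(1, 3))

  # zero-weight inner maps with biases: f = c + sum s_k exp(c_k), constant in T
  p2 <- exposure_params(inner_weights = matrix(0, 3, 2),
                        inner_bias = c(0.5, -1, 2),
                        mix_weights = c(1, 2, 0.5), mix_bias = 0.25)
  want <- 0.25 + sum(c(1, 2, 0.5) * exp(c(0.5, -1, 2)))
  expect_equal(response_factor(p2, matrix(rnorm(10), 5, 2)), rep(want, 5))

  # hand-set: g_1(T) = 0.1 (mean(T) - 20), at constant 30 C: f = e^1
  l <- 7
  p3 <- exposure_params(inner_weights = matrix(0.1 / (l + 1), 1, l + 1),
                        inner_bias = -2, mix_weights = 1, mix_bias = 0)
  expect_equal(response_factor(p3, matrix(30, 1, l + 1)), exp(1),
               tolerance = 1e-12)

  expect_error(response_factor(p3, matrix(30, 1, 3)), "lag vectors")
  expect_error(exposure_params(inner_weights = matrix(0, 1, 2), inner_bias = 0,
                               mix_weights = -1, mix_bias = 0),
               "non-negative|>= 0")
})

test_that("expected-deaths arithmetic multiplies baseline, population, factor, dow", {
  days <- as.Date("2020-06-01") + 0:6 # Monday-Sunday
  popd <- tibble::tibble(date = rep(days, 2),
                         district_id = "D1",
                         sex = rep(c("f", "m"), each = 7),
                         age_band = "80-85",
                         pop = 1e6)
  bl <- tibble::tibble(sex = c("f", "m"), age_band = "80-85",
                       log_daily_rate0 = log(1e-5), trend_per_year = 0)
  out <- expected_deaths(popd, bl, factors = tibble::tibble(district_id = "D1",
                                                            factor = 1.2))
  expect_equal(out$expected, rep(12, 14), tolerance = 1e-12)

  # zero population stratum gives zero expected deaths
  popd0 <- popd |> dplyr::mutate(pop = ifelse(sex == "m", 0, pop))
  out0 <- expected_deaths(popd0, bl)
  expect_true(all(out0$expected[out0$sex == "m"] == 0))

  # dow factors modulate by weekday
  dowf <- c(1.4, 1, 1, 1, 1, 1, 0.6)
  outd <- expected_deaths(popd, bl, dow_factors = dowf)
  expect_equal(outd$expected[1], 10 * 1.4) # 2020-06-01 is a Monday
  expect_equal(outd$expected[7], 10 * 0.6) # Sunday
})

test_that("poisson loss matches the closed form and is minimised at lambda = y", {
  expect_equal(poisson_nll(1, 1), 1)
  expect_equal(poisson_nll(2, 0), 2)
  expect_equal(poisson_nll(c(1, 2), c(1, 0)), 3)
  # stationary point of lambda - y log(lambda) at lambda = y
  y <- 7
  lams <- seq(5, 9, by = 0.05)
  losses <- vapply(lams, function(l) poisson_nll(l, y), numeric(1))
  expect_equal(lams[which.min(losses)], y)
  expect_error(poisson_nll(-1, 0), "non-negative")
})

test_that("poisson loss gradient matches central finite differences", {
  set.seed(31)
  lam <- runif(50, 0.5, 30)
  y <- rpois(50, lam)
  g_analytic <- 1 - y / lam
  h <- 1e-6 * lam
  g_num <- vapply(seq_along(lam), function(i) {
    lp <- lam; lm_ <- lam
    lp[i] <- lp[i] + h[i]; lm_[i] <- lm_[i] - h[i]
    (poisson_nll(lp, y) - poisson_nll(lm_, y)) / (2 * h[i])
  }, numeric(1))
  expect_equal(g_num, g_analytic, tolerance = 1e-6)
})

test_that("training-engine gradient matches finite differences end to end", {
  region <- small_region()
  wx <- small_weather()
  streams <- small_streams()
  for (variant in c("exponential", "linear")) {
    tc <- train_config(train_years = 2019, validation_years = 2020,
                       ensemble_size = 1, l = 3, d = 2, seed = 5,
                       variant = variant)
    ctx <- heatmort:::build_fit_context(streams, wx$district_temps, region, tc)
    lay <- heatmort:::theta_layout(tc)
    theta <- heatmort:::init_theta(ctx, lay, 11)
    set.seed(1)
    theta <- theta + rnorm(length(theta), 0, 0.03)
    loss_at <- function(th) {
      fwd <- heatmort:::model_forward(heatmort:::unpack_theta(th, lay), ctx)
      heatmort:::stream_losses(fwd, ctx, "train")$loss
    }
    fwd <- heatmort:::model_forward(heatmort:::unpack_theta(theta, lay), ctx)
    g <- heatmort:::model_backward(heatmort:::unpack_theta(theta, lay), fwd,
                                   ctx, lay)
    set.seed(2)
    idx <- sort(sample(length(theta), 25))
    num <- vapply(idx, function(i) {
      h <- 1e-5 * max(1, abs(theta[i]))
      tp <- theta; tp[i] <- tp[i] + h
      tm_ <- theta; tm_[i] <- tm_[i] - h
      (loss_at(tp) - loss_at(tm_)) / (2 * h)
    }, numeric(1))
    rel <- abs(num - g[idx]) / pmax(abs(num), abs(g[idx]), 1e-6)
    # ReLU kinks make central differences slightly biased for the linear variant
    expect_lt(max(rel), if (variant == "exponential") 1e-4 else 5e-3)
  }
})

test_that("model aggregation conserves totals between daily and stream cells", {
  region <- small_region()
  wx <- small_weather()
  streams <- small_streams()
  tc <- train_config(train_years = 2019, validation_years = 2020,
                     ensemble_size = 1, seed = 5, l = 3, d = 2)
  ctx <- heatmort:::build_fit_context(streams, wx$district_temps, region, tc)
  lay <- heatmort:::theta_layout(tc)
  fwd <- heatmort:::model_forward(
    heatmort:::unpack_theta(heatmort:::init_theta(ctx, lay, 11), lay), ctx)
  daily_total <- sum(Reduce(`+`, fwd$Dg))
  expect_equal(sum(fwd$lam1), daily_total, tolerance = 1e-9)
  # weekly streams cover the kept weeks only
  kept_days <- !is.na(ctx$week_idx)
  weekly_total <- sum(Reduce(`+`, fwd$Dg)[, kept_days])
  expect_equal(sum(fwd$lam2), weekly_total, tolerance = 1e-9)
  expect_equal(sum(fwd$lam3), weekly_total, tolerance = 1e-9)
})

test_that("day-of-week parameterisation always yields mean-1 factors", {
  for (i in 1:5) {
    set.seed(i)
    delta <- rnorm(7, 0, 1)
    u <- exp(delta)
    w <- u / mean(u)
    expect_equal(mean(w), 1, tolerance = 1e-14)
    expect_true(all(w > 0))
  }
})

test_that("a small ensemble trains, improves the loss, and averages correctly", {
  region <- small_region()
  wx <- small_weather()
  streams <- small_streams()
  tc <- train_config(train_years = 2019, validation_years = 2020,
                     ensemble_size = 2, seed = 5, l = 3, d = 2,
                     lr = 0.01, epochs = 60, patience = 60,
                     variant = "linear")
  fit <- train_ensemble(streams, wx$district_temps, region, tc)
  expect_s3_class(fit, "exposure_fit")
  expect_equal(nrow(fit$fit_report), 2)

  # ensemble mean equals the mean of per-instance predictions
  mean_pred <- predict_expected_deaths(fit, wx$district_temps,
                                       level = "national_day")
  all_pred <- predict_expected_deaths(fit, wx$district_temps,
                                      level = "national_day",
                                      instances = "all")
  manual <- all_pred |>
    dplyr::group_by(date) |>
    dplyr::summarise(expected = mean(expected), .groups = "drop")
  expect_equal(mean_pred$expected, manual$expected, tolerance = 1e-10)

  # predictions are positive and of a sane total magnitude
  obs_total <- sum(streams$daily_state_sex$deaths)
  expect_true(all(mean_pred$expected > 0))
  expect_lt(abs(sum(mean_pred$expected) - obs_total) / obs_total, 0.2)
})

test_that("ensemble of identical seeds has zero spread", {
  region <- small_region()
  wx <- small_weather()
  streams <- small_streams()
  tc <- train_config(train_years = 2019, validation_years = 2020,
                     ensemble_size = 2, seeds = c(9, 9), l = 2, d = 2,
                     lr = 0.01, epochs = 20, patience = 20)
  fit <- train_ensemble(streams, wx$district_temps, region, tc)
  p <- predict_expected_deaths(fit, wx$district_temps, level = "national_day",
                               instances = "all")
  spread <- p |>
    dplyr::group_by(date) |>
    dplyr::summarise(s = sd(expected), .groups = "drop")
  expect_true(all(spread$s == 0))
})

test_that("training configuration rejects inconsistent inputs", {
  expect_error(train_config(train_years = 2019, validation_years = 2019),
               "disjoint")
  expect_error(train_config(ensemble_size = 0), "ensemble_size")
  expect_error(train_config(ensemble_size = 3, seeds = c(1, 2)), "seeds")
})
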