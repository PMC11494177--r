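#' Ground-truth temperature-risk model for the synthetic generator
#'
#' A known exposure-response used to simulate deaths:
#' `f(T) = 1 + slope * max(0, sum(lag_weights * T) - threshold)^exponent`,
#' applied to the lag vector `T = [T_t, ..., T_{t-l}]`, together with
#' multiplicative day-of-week reporting factors whose mean is exactly 1.
#'
#' @param lag_weights Non-negative weights over the lag window (same-day
#'   first); normalised to sum to 1. Length sets the lag order `l + 1`.
#' @param threshold Temperature threshold in degrees Celsius above which risk
#'   rises (default 20, the conventional cap for "no heat" conditions).
#' @param slope Risk increase per degree(^exponent) above the threshold (>= 0).
#' @param exponent Shape of the response above the threshold (>= 1).
#' @param dow_factors Seven positive day-of-week factors (Monday first);
#'   normalised so their mean is exactly 1.
#' @return An object of class `true_risk_model`.
#' @examples
#' trm <- true_risk_model(slope = 0.05)
#' risk_factor(trm, matrix(c(25, 24, 22, 21, 20, 19, 18, 18), nrow = 1))
#' @export
true_risk_model <- function(lag_weights = c(0.35, 0.25, 0.18, 0.12, 0.05, 0.03, 0.015, 0.005),
                            threshold = 20,
                            slope = 0.03,
                            exponent = 1.5,
                            dow_factors = c(1.02, 1.01, 1, 0.99, 0.98, 0.99, 1.01)) {
  assert_that(all(lag_weights >= 0) && sum(lag_weights) > 0,
              "lag_weights must be non-negative, not all zero")
  assert_that(slope >= 0, "slope must be >= 0")
  assert_that(exponent >= 1, "exponent must be >= 1")
  assert_that(length(dow_factors) == 7 && all(dow_factors > 0),
              "dow_factors must be 7 positive values")
  structure(
    list(
      lag_weights = lag_weights / sum(lag_weights),
      threshold = threshold, slope = slope, exponent = exponent,
      dow_factors = dow_factors / mean(dow_factors)
    ),
    class = "true_risk_model"
  )
}

#' Evaluate the ground-truth risk factor on lag vectors
#'
#' @param model A [true_risk_model()].
#' @param lag_mat Matrix of lag vectors (rows = observations, columns =
#'   `lag0 ... lagl`), e.g. from [build_lag_matrix()].
#' @return Numeric vector of risk factors `>= 1`.
#' @export
risk_factor <- function(model, lag_mat) {
  assert_that(ncol(lag_mat) == length(model$lag_weights),
              "lag matrix width does not match lag_weights length")
  eff <- as.vector(lag_mat %*% model$lag_weights)
  1 + model$slope * pmax(0, eff - model$threshold)^model$exponent
}
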