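# The exposure-response function f maps a lag vector of daily mean
# temperatures T = [T_t, T_{t-1}, ..., T_{t-l}] to a non-negative multiplying
# factor on baseline mortality. Two variants:
#
#   exponential: f(T) = c + sum_k s_k exp(g_k(T)),  s_k >= 0, c >= 0,
#     with g_k affine — a sum of exponential terms, a shape unavailable to
#     classical GAM/DLM formulations;
#   linear: f(T) = softplus(v0 + sum_k v_k relu(g_k(T))) — a size-(l+1)
#     1-d convolution (the affine maps g_k over the full lag window) followed
#     by a rectified fully connected layer, squashed to non-negative output.
#
# Non-negativity of the exponential variant's mixing weights and bias is
# structural (softplus reparameterisation during training), never clipping.

#' Construct exposure-response parameters
#'
#' @param variant `"exponential"` or `"linear"`.
#' @param inner_weights `d x (l+1)` matrix: the affine maps' weights over the
#'   lag vector (same-day temperature first).
#' @param inner_bias Length-`d` intercepts of the affine maps.
#' @param mix_weights Length-`d` output mixing weights; must be `>= 0` for the
#'   exponential variant.
#' @param mix_bias Scalar output bias; must be `>= 0` for the exponential
#'   variant.
#' @return Object of class `exposure_params` with fields `variant`, `l`, `d`
#'   and the weights.
#' @examples
#' # d = 1, g_1(T) = 0.1 * (mean(T) - 20): f = exp(1) at a constant 30 C week
#' p <- exposure_params(inner_weights = matrix(0.1 / 8, 1, 8),
#'                      inner_bias = -2, mix_weights = 1, mix_bias = 0)
#' response_factor(p, matrix(30, 1, 8))
#' @export
exposure_params <- function(variant = c("exponential", "linear"),
                            inner_weights, inner_bias, mix_weights, mix_bias) {
  variant <- match.arg(variant)
  inner_weights <- as.matrix(inner_weights)
  d <- nrow(inner_weights)
  l <- ncol(inner_weights) - 1
  assert_that(l >= 0 && d >= 1, "need l >= 0 and d >= 1")
  assert_that(length(inner_bias) == d, "inner_bias must have length d")
  assert_that(length(mix_weights) == d, "mix_weights must have length d")
  assert_that(length(mix_bias) == 1, "mix_bias must be a scalar")
  if (variant == "exponential") {
    assert_that(all(mix_weights >= 0) && mix_bias >= 0,
                "exponential variant requires mix_weights >= 0 and mix_bias >= 0")
  }
  structure(
    list(variant = variant, l = l, d = d,
         inner_weights = inner_weights, inner_bias = as.numeric(inner_bias),
         mix_weights = as.numeric(mix_weights), mix_bias = as.numeric(mix_bias)),
    class = "exposure_params"
  )
}

#' Evaluate the exposure-response factor on lag vectors
#'
#' @param params An [exposure_params()].
#' @param lag_mat Matrix of lag vectors, `l + 1` columns (same-day first),
#'   e.g. from [build_lag_matrix()].
#' @return Numeric vector of non-negative multiplying factors, one per row.
#' @export
response_factor <- function(params, lag_mat) {
  lag_mat <- if (is.matrix(lag_mat)) lag_mat else matrix(lag_mat, nrow = 1)
  assert_that(ncol(lag_mat) == params$l + 1,
              sprintf("lag vectors have %d entries, params expect %d",
                      ncol(lag_mat), params$l + 1))
  Z <- tcrossprod(lag_mat, params$inner_weights)
  Z <- sweep(Z, 2, params$inner_bias, `+`)
  if (params$variant == "exponential") {
    as.vector(exp(Z) %*% params$mix_weights) + params$mix_bias
  } else {
    softplus(as.vector(pmax(Z, 0) %*% params$mix_weights) + params$mix_bias)
  }
}

#' @export
print.exposure_params <- function(x, ...) {
  cat(sprintf("<exposure_params> %s variant, lag window l = %d, hidden d = %d\n",
              x$variant, x$l, x$d))
  invisible(x)
}
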