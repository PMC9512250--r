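#' Sample a noisy percept of object position and velocity
#'
#' The observer's point estimates of position and velocity are corrupted by
#' independent Gaussian noise with SDs `sigma_x` and `sigma_v`.  A raw
#' position sample falling inside the body (< 0) is replaced by 0.1 cm,
#' i.e. immediately in front of the body surface; velocity samples are
#' never clamped.
#'
#' @param x True object distance from the body surface (cm, >= 0; the body
#'   is at 0 and positive values are in front of it).
#' @param v True signed velocity (cm/s; negative = looming toward the body).
#' @param params A [pps_params()] object.
#' @param n Number of independent percepts to draw.
#' @return A data frame with `n` rows and columns `x_hat`, `v_hat`, plus
#'   the encoding uncertainties `sigma_x`, `sigma_v` carried unchanged.
#' @examples
#' set.seed(1)
#' sample_percept(30, -25, pps_params(), n = 3)
#' @export
sample_percept <- function(x, v, params = pps_params(), n = 1L) {
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0,
            is.numeric(v), length(v) == 1L,
            inherits(params, "pps_params"), n >= 1)
  x_hat <- stats::rnorm(n, mean = x, sd = params$sigma_x)
  x_hat[x_hat < 0] <- 0.1
  v_hat <- stats::rnorm(n, mean = v, sd = params$sigma_v)
  data.frame(x_hat = x_hat, v_hat = v_hat,
             sigma_x = params$sigma_x, sigma_v = params$sigma_v)
}

#' Belief about the object's future position
#'
#' Given a percept encoded as normal distributions `N(x_hat, sigma_x)` and
#' `N(v_hat, sigma_v)`, the displacement over the horizon `delta_t` is
#' `N(delta_t * v_hat, delta_t * sigma_v)` and the future position is their
#' sum:
#' `N(mu = x_hat + delta_t * v_hat, sigma = sqrt(sigma_x^2 + (delta_t * sigma_v)^2))`.
#'
#' @param x_hat,v_hat Point estimates of position (cm) and velocity (cm/s);
#'   vectorised.
#' @param params A [pps_params()] object supplying `sigma_x`, `sigma_v`,
#'   `delta_t`.
#' @return A list with components `mu` (vector, cm) and `sigma` (scalar,
#'   cm).
#' @examples
#' future_belief(32, -48, pps_params(sigma_x = 4, sigma_v = 5))
#' @export
future_belief <- function(x_hat, v_hat, params = pps_params()) {
  stopifnot(is.numeric(x_hat), is.numeric(v_hat),
            length(x_hat) == length(v_hat), inherits(params, "pps_params"))
  list(mu = x_hat + params$delta_t * v_hat,
       sigma = sqrt(params$sigma_x^2 + (params$delta_t * params$sigma_v)^2))
}

#' Probability that the object contacts the body within the horizon
#'
#' Contact (`y = 1`) occurs when the future position is at or behind the
#' body surface, so the hit probability is the lower-tail mass of the
#' future-position belief at 0: `pnorm(0, mu, sigma)`.  In the degenerate
#' noiseless case `sigma = 0` the belief is a point mass and the
#' probability is 1 when `mu <= 0`, else 0.
#'
#' @param mu Mean(s) of the future-position belief (cm); vectorised.
#' @param sigma SD of the belief (cm, >= 0; scalar or same length as `mu`).
#' @return Hit probabilities in \[0, 1\], same length as `mu`.
#' @examples
#' hit_probability(0, 4.717)   # 0.5: belief centred on the body surface
#' hit_probability(8, 4.717)   # ~0.045
#' @export
hit_probability <- function(mu, sigma) {
  stopifnot(is.numeric(mu), is.numeric(sigma), all(sigma >= 0),
            length(sigma) == 1L || length(sigma) == length(mu))
  sigma <- rep_len(sigma, length(mu))
  p <- numeric(length(mu))
  degenerate <- sigma == 0
  p[degenerate] <- as.numeric(mu[degenerate] <= 0)
  if (any(!degenerate)) {
    p[!degenerate] <- stats::pnorm(0, mean = mu[!degenerate],
                                   sd = sigma[!degenerate])
  }
  p
}

#' Loss incurred by a graded contact prediction
#'
#' Asymmetric loss
#' `loss(y, y_pred) = FP * max(0, y_pred - y)^r + FN * max(0, y - y_pred)^r`:
#' over-prediction is penalised by the false-positive factor, under-prediction
#' by the false-negative factor, each raised to the exponent `r`.
#'
#' @param y Actual outcome(s), 0 (no contact) or 1 (contact).
#' @param y_pred Graded prediction(s) in \[0, 1\].
#' @param params A [pps_params()] object supplying `fn`, `fp`, `r`.
#' @return Non-negative loss values.
#' @examples
#' loss_value(1, 0.5, pps_params())   # 5 * 0.25 = 1.25
#' @export
loss_value <- function(y, y_pred, params = pps_params()) {
  stopifnot(all(y %in% c(0, 1)))
  if (any(y_pred < 0 | y_pred > 1)) {
    stop("`y_pred` must lie in [0, 1]", call. = FALSE)
  }
  params$fp * pmax(0, y_pred - y)^params$r +
    params$fn * pmax(0, y - y_pred)^params$r
}

#' Expected loss of a graded prediction under the hit probability
#'
#' `L(p, y_pred) = p * loss(1, y_pred) + (1 - p) * loss(0, y_pred)`, which
#' for the default exponent `r = 2` expands to
#' `p * FN * (1 - y_pred)^2 + (1 - p) * FP * y_pred^2`.
#'
#' @param p_hit Hit probability(ies) in \[0, 1\].
#' @param y_pred Graded prediction(s) in \[0, 1\].
#' @param params A [pps_params()] object.
#' @return Non-negative expected losses (recycled to the common length).
#' @examples
#' expected_loss(0.5, 0.5, pps_params())   # 0.75 at FN = 5, FP = 1
#' @export
expected_loss <- function(p_hit, y_pred, params = pps_params()) {
  if (any(p_hit < 0 | p_hit > 1)) {
    stop("`p_hit` must lie in [0, 1]", call. = FALSE)
  }
  p_hit * loss_value(1, y_pred, params) +
    (1 - p_hit) * loss_value(0, y_pred, params)
}

#' Bayes-optimal contact prediction by grid minimisation
#'
#' Evaluates the expected loss on the candidate grid
#' `{0, grid_step, 2 * grid_step, ..., 1}` and returns the candidate with
#' the smallest expected loss (ties broken toward the smaller candidate).
#' This mirrors the discretised argmin used in the simulation experiments;
#' [optimal_prediction_cf()] gives the exact `r = 2` minimiser.
#'
#' @param p_hit Hit probability(ies) in \[0, 1\]; vectorised.
#' @param params A [pps_params()] object.
#' @param grid_step Optional override of `params$grid_step`.
#' @return Optimal prediction(s) `y*` on the grid, same length as `p_hit`.
#' @examples
#' optimal_prediction(c(0, 0.5, 1), pps_params(fn = 1, fp = 1))
#' @export
optimal_prediction <- function(p_hit, params = pps_params(),
                               grid_step = NULL) {
  if (any(p_hit < 0 | p_hit > 1)) {
    stop("`p_hit` must lie in [0, 1]", call. = FALSE)
  }
  step <- if (is.null(grid_step)) params$grid_step else grid_step
  stopifnot(is.numeric(step), length(step) == 1L, step > 0, step <= 1)
  grid <- seq(0, 1, by = step)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  # expected-loss matrix: rows = probabilities, columns = candidates
  el <- outer(p_hit, params$fn * (1 - grid)^params$r) +
    outer(1 - p_hit, params$fp * grid^params$r)
  grid[max.col(-el, ties.method = "first")]
}

#' Closed-form Bayes-optimal contact prediction (quadratic loss)
#'
#' For exponent `r = 2` the expected loss is quadratic in the prediction
#' and its unique minimiser on \[0, 1\] is
#' `p * FN / (p * FN + (1 - p) * FP)`.  Used as the analytic counterpart
#' of the grid search.
#'
#' @inheritParams optimal_prediction
#' @return Optimal prediction(s) in \[0, 1\].
#' @examples
#' optimal_prediction_cf(0.5, pps_params())   # 2.5/3
#' @export
optimal_prediction_cf <- function(p_hit, params = pps_params()) {
  if (params$r != 2) {
    stop("closed form requires loss exponent r = 2", call. = FALSE)
  }
  if (any(p_hit < 0 | p_hit > 1)) {
    stop("`p_hit` must lie in [0, 1]", call. = FALSE)
  }
  num <- p_hit * params$fn
  den <- num + (1 - p_hit) * params$fp
  out <- num / den
  out[den == 0] <- 0  # fn = 0 and p = 0, or fp = 0 and p = 0
  out
}

#' One stochastic draw of the full 1D impact-prediction pipeline
#'
#' Composes percept sampling, future-position belief, hit probability and
#' grid-minimised optimal prediction: each draw yields one optimal graded
#' contact prediction `y*` for the given true object state.  Repeated
#' draws differ through the perceptual noise; with zero noise the pipeline
#' is deterministic.
#'
#' @inheritParams sample_percept
#' @param n Number of independent pipeline draws.
#' @return Numeric vector of `n` optimal predictions in \[0, 1\].
#' @examples
#' set.seed(1)
#' mean(predict_impact(30, -25, pps_params(), n = 100))
#' @export
predict_impact <- function(x, v, params = pps_params(), n = 1L) {
  percept <- sample_percept(x, v, params, n = n)
  belief <- future_belief(percept$x_hat, percept$v_hat, params)
  p_hit <- hit_probability(belief$mu, belief$sigma)
  optimal_prediction(p_hit, params)
}
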