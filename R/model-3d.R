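#' Sample a noisy 3D percept
#'
#' Each axis is sampled independently as in the 1D model.  Only the axis-1
#' (depth) position sample is clamped to 0.1 cm when it falls behind the
#' collision plane; lateral axes are unclamped.
#'
#' @param x True position vector (3 components, cm; axis 1 = depth toward
#'   the body, `x[1] >= 0`).
#' @param v True velocity vector (3 components, cm/s; negative axis-1
#'   velocity = looming).
#' @param params A [pps_params_3d()] object.
#' @param n Number of independent percepts.
#' @return A list with `n x 3` matrices `x_hat` and `v_hat`.
#' @examples
#' set.seed(1)
#' sample_percept_3d(c(30, 0, 0), c(-25, 0, 0), pps_params_3d())
#' @export
sample_percept_3d <- function(x, v, params = pps_params_3d(), n = 1L) {
  stopifnot(is.numeric(x), length(x) == 3L, x[1] >= 0,
            is.numeric(v), length(v) == 3L,
            inherits(params, "pps_params_3d"), n >= 1)
  x_hat <- vapply(1:3, function(i) stats::rnorm(n, x[i], params$sigma_x[i]),
                  numeric(n))
  v_hat <- vapply(1:3, function(i) stats::rnorm(n, v[i], params$sigma_v[i]),
                  numeric(n))
  x_hat <- matrix(x_hat, nrow = n, ncol = 3L)
  v_hat <- matrix(v_hat, nrow = n, ncol = 3L)
  x_hat[x_hat[, 1] < 0, 1] <- 0.1
  list(x_hat = x_hat, v_hat = v_hat)
}

#' Does a sampled future position count as a body hit?
#'
#' A future position counts as a hit when it lies at or behind the
#' collision plane (`future[1] <= 0`) and the straight segment from the
#' perceived current position to it crosses the plane inside the body
#' rectangle.  The crossing point is
#' `c_i = p_i + t * (f_i - p_i)` with `t = p1 / (p1 - f1)`, and the hit
#' condition is `|c_2| <= r1` and `|c_3| <= r2`.
#'
#' @param future Future position(s): numeric vector of 3 or an `n x 3`
#'   matrix.
#' @param percept Perceived current position(s): vector of 3 or an
#'   `n x 3` matrix; every axis-1 component must be positive (in front of
#'   the plane).
#' @param body A [body_rect()].
#' @return Logical vector of hit indicators.
#' @examples
#' hit_test(c(-1, 0, 0), c(10, 0, 0), body_part("face"))   # TRUE
#' @export
hit_test <- function(future, percept, body) {
  stopifnot(inherits(body, "body_rect"))
  if (is.null(dim(future))) future <- matrix(future, ncol = 3L)
  if (is.null(dim(percept))) percept <- matrix(percept, ncol = 3L)
  if (nrow(percept) == 1L && nrow(future) > 1L) {
    percept <- percept[rep(1L, nrow(future)), , drop = FALSE]
  }
  stopifnot(ncol(future) == 3L, ncol(percept) == 3L,
            nrow(future) == nrow(percept))
  if (any(percept[, 1] <= 0)) {
    stop("perceived position must be in front of the collision plane ",
         "(axis-1 component > 0)", call. = FALSE)
  }
  hit <- rep(FALSE, nrow(future))
  behind <- future[, 1] <= 0
  if (any(behind)) {
    p1 <- percept[behind, 1]
    t <- p1 / (p1 - future[behind, 1])
    c2 <- percept[behind, 2] + t * (future[behind, 2] - percept[behind, 2])
    c3 <- percept[behind, 3] + t * (future[behind, 3] - percept[behind, 3])
    hit[behind] <- abs(c2) <= body$r1 & abs(c3) <= body$r2
  }
  hit
}

#' Monte-Carlo hit probability for a 3D percept
#'
#' Draws `n_mc` future positions from the trivariate future-position
#' belief (diagonal covariance; per-axis
#' `mu_i = x_hat_i + delta_t * v_hat_i`,
#' `sigma_i = sqrt(sigma_x_i^2 + (delta_t * sigma_v_i)^2)`) and returns
#' the fraction that pass [hit_test()] against the body rectangle, an
#' estimate of the hit-probability integral over the hit region.
#'
#' @param x_hat Perceived position (3 components, `x_hat[1] > 0`).
#' @param v_hat Perceived velocity (3 components).
#' @param body A [body_rect()].
#' @param params A [pps_params_3d()] object.
#' @return Scalar hit-probability estimate in \[0, 1\].
#' @examples
#' set.seed(1)
#' hit_probability_3d(c(10, 0, 0), c(-25, 0, 0), body_part("face"),
#'                    pps_params_3d())
#' @export
hit_probability_3d <- function(x_hat, v_hat, body, params = pps_params_3d()) {
  stopifnot(is.numeric(x_hat), length(x_hat) == 3L,
            is.numeric(v_hat), length(v_hat) == 3L,
            inherits(body, "body_rect"), inherits(params, "pps_params_3d"))
  mu <- x_hat + params$delta_t * v_hat
  sig <- sqrt(params$sigma_x^2 + (params$delta_t * params$sigma_v)^2)
  f <- vapply(1:3, function(i) stats::rnorm(params$n_mc, mu[i], sig[i]),
              numeric(params$n_mc))
  mean(hit_test(f, x_hat, body))
}

#' Stochastic draws of the full 3D impact-prediction pipeline
#'
#' Composes 3D percept sampling, Monte-Carlo hit-probability estimation
#' and the grid-minimised optimal prediction (the decision stage is shared
#' with the 1D model: it acts on the scalar hit probability).
#'
#' @inheritParams sample_percept_3d
#' @param body A [body_rect()].
#' @param n Number of independent pipeline draws; each draw uses a fresh
#'   percept and fresh `n_mc` future-position samples.
#' @return Numeric vector of `n` optimal predictions in \[0, 1\].
#' @examples
#' set.seed(1)
#' predict_impact_3d(c(30, 0, 0), c(-25, 0, 0), body_part("face"),
#'                   pps_params_3d(n_mc = 1000), n = 5)
#' @export
predict_impact_3d <- function(x, v, body, params = pps_params_3d(), n = 1L) {
  stopifnot(inherits(body, "body_rect"), inherits(params, "pps_params_3d"))
  p_hit <- .hit_prob_3d_batch(x, v, body, params, n)
  optimal_prediction(p_hit, params)
}

# Vectorised production path for sweeps: n independent (percept +
# Monte-Carlo) draws at one true state.  Lateral future-position
# components are drawn only for samples already behind the collision
# plane; hit status is FALSE regardless of the lateral draw otherwise,
# so the estimate's distribution is unchanged while the cost drops by the
# fraction of in-front samples.
.hit_prob_3d_batch <- function(x, v, body, params, n) {
  n <- as.integer(n)
  n_mc <- params$n_mc
  dT <- params$delta_t
  percept <- sample_percept_3d(x, v, params, n = n)
  mu <- percept$x_hat + dT * percept$v_hat        # n x 3
  sig <- sqrt(params$sigma_x^2 + (dT * params$sigma_v)^2)

  # axis-1 future samples for all reps: column j = rep j
  f1 <- rep(mu[, 1], each = n_mc) + sig[1] * stats::rnorm(n * n_mc)
  idx <- which(f1 <= 0)
  counts <- integer(n)
  if (length(idx)) {
    rep_id <- (idx - 1L) %/% n_mc + 1L
    f2 <- mu[rep_id, 2] + sig[2] * stats::rnorm(length(idx))
    f3 <- mu[rep_id, 3] + sig[3] * stats::rnorm(length(idx))
    p1 <- percept$x_hat[rep_id, 1]
    t <- p1 / (p1 - f1[idx])
    c2 <- percept$x_hat[rep_id, 2] + t * (f2 - percept$x_hat[rep_id, 2])
    c3 <- percept$x_hat[rep_id, 3] + t * (f3 - percept$x_hat[rep_id, 3])
    hit <- abs(c2) <= body$r1 & abs(c3) <= body$r2
    counts <- tabulate(rep_id[hit], nbins = n)
  }
  counts / n_mc
}
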