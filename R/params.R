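#' Model parameters for the 1D impact-prediction observer
#'
#' Bundles the perceptual uncertainties, loss factors and prediction horizon
#' of the Bayesian impact-prediction model.  Defaults are the baseline
#' parameter set used throughout the simulation experiments: an object
#' approaching at 25 cm/s is perceived with position noise 2.5 cm and
#' velocity noise 20 cm/s, a missed contact (false negative) costs five
#' times as much as a falsely predicted one, and contact is predicted over
#' a 0.5 s horizon.
#'
#' @param sigma_x Position-estimation noise SD (cm, >= 0).
#' @param sigma_v Velocity-estimation noise SD (cm/s, >= 0).
#' @param fn False-negative loss factor (>= 0): cost of experiencing contact
#'   that was not predicted.
#' @param fp False-positive loss factor (>= 0): cost of predicting contact
#'   that does not occur.  `fn + fp` must be positive.
#' @param r Loss exponent shaping the loss function; the closed-form optimum
#'   is available only for the default `r = 2`.
#' @param delta_t Prediction horizon (s, > 0): the interval over which
#'   contact is predicted, interpretable as the time needed to execute a
#'   defensive action.
#' @param grid_step Spacing of the candidate-prediction grid on \[0, 1\]
#'   over which the expected loss is minimised (default 0.05).
#'
#' @return An object of class `pps_params`.
#' @seealso [pps_params_3d()], [predict_impact()]
#' @examples
#' pps_params()                  # baseline
#' pps_params(sigma_v = 35)      # noisier velocity percepts
#' @export
pps_params <- function(sigma_x = 2.5, sigma_v = 20, fn = 5, fp = 1,
                       r = 2, delta_t = 0.5, grid_step = 0.05) {
  stopifnot(
    is.numeric(sigma_x), length(sigma_x) == 1L, sigma_x >= 0,
    is.numeric(sigma_v), length(sigma_v) == 1L, sigma_v >= 0,
    is.numeric(fn), length(fn) == 1L, fn >= 0,
    is.numeric(fp), length(fp) == 1L, fp >= 0,
    is.numeric(r), length(r) == 1L, r > 0,
    is.numeric(delta_t), length(delta_t) == 1L, delta_t > 0,
    is.numeric(grid_step), length(grid_step) == 1L,
    grid_step > 0, grid_step <= 1
  )
  if (fn + fp <= 0) {
    stop("at least one of `fn`, `fp` must be positive", call. = FALSE)
  }
  structure(
    list(sigma_x = sigma_x, sigma_v = sigma_v, fn = fn, fp = fp, r = r,
         delta_t = delta_t, grid_step = grid_step),
    class = "pps_params"
  )
}

#' @export
print.pps_params <- function(x, ...) {
  cat("<pps_params>\n")
  cat(sprintf("  sigma_x = %g cm, sigma_v = %g cm/s\n", x$sigma_x, x$sigma_v))
  cat(sprintf("  FN = %g, FP = %g, r = %g\n", x$fn, x$fp, x$r))
  cat(sprintf("  delta_t = %g s, grid_step = %g\n", x$delta_t, x$grid_step))
  invisible(x)
}

#' Model parameters for the 3D impact-prediction observer
#'
#' Per-axis generalisation of [pps_params()].  Axis 1 points away from the
#' body along the approach direction (depth); axes 2 and 3 are the
#' horizontal and vertical directions spanning the body-part collision
#' plane.  Position and velocity percepts are sampled independently per
#' axis, and the future-position belief is a trivariate normal with
#' diagonal covariance.
#'
#' @param sigma_x Numeric vector of 3 per-axis position noise SDs (cm).
#' @param sigma_v Numeric vector of 3 per-axis velocity noise SDs (cm/s).
#' @param fn,fp,r,delta_t,grid_step As in [pps_params()].
#' @param n_mc Number of Monte-Carlo samples of the future position used to
#'   estimate the hit probability (default 10000).
#'
#' @return An object of class `pps_params_3d`.
#' @examples
#' pps_params_3d(sigma_v = c(30, 40, 40), sigma_x = c(2.5, 5, 5))
#' @export
pps_params_3d <- function(sigma_x = c(2.5, 0, 0), sigma_v = c(20, 0, 0),
                          fn = 5, fp = 1, r = 2, delta_t = 0.5,
                          grid_step = 0.05, n_mc = 10000L) {
  stopifnot(
    is.numeric(sigma_x), length(sigma_x) == 3L, all(sigma_x >= 0),
    is.numeric(sigma_v), length(sigma_v) == 3L, all(sigma_v >= 0),
    is.numeric(n_mc), length(n_mc) == 1L, n_mc >= 1
  )
  base <- pps_params(sigma_x = 1, sigma_v = 1, fn = fn, fp = fp, r = r,
                     delta_t = delta_t, grid_step = grid_step)
  structure(
    list(sigma_x = as.numeric(sigma_x), sigma_v = as.numeric(sigma_v),
         fn = base$fn, fp = base$fp, r = base$r, delta_t = base$delta_t,
         grid_step = base$grid_step, n_mc = as.integer(n_mc)),
    class = "pps_params_3d"
  )
}

#' @export
print.pps_params_3d <- function(x, ...) {
  cat("<pps_params_3d>\n")
  cat(sprintf("  sigma_x = [%s] cm, sigma_v = [%s] cm/s\n",
              paste(x$sigma_x, collapse = ", "),
              paste(x$sigma_v, collapse = ", ")))
  cat(sprintf("  FN = %g, FP = %g, r = %g\n", x$fn, x$fp, x$r))
  cat(sprintf("  delta_t = %g s, grid_step = %g, n_mc = %d\n",
              x$delta_t, x$grid_step, x$n_mc))
  invisible(x)
}

#' Rectangular body-part collision plane
#'
#' A body part is represented by its 2D collision rectangle embedded in 3D
#' space at depth 0, centred on the origin, with half-width `r1` along
#' axis 2 and half-height `r2` along axis 3 (full size `[2*r1, 2*r2]`).
#' The depth of the body part is not modelled.
#'
#' @param width Full width of the rectangle (cm, > 0).
#' @param height Full height of the rectangle (cm, > 0).
#' @return An object of class `body_rect` with fields `r1`, `r2`
#'   (half-extents).
#' @examples
#' body_rect(25, 25)    # face
#' body_part("torso")   # equivalent to body_rect(50, 50)
#' @export
body_rect <- function(width, height = width) {
  stopifnot(is.numeric(width), length(width) == 1L, width > 0,
            is.numeric(height), length(height) == 1L, height > 0)
  structure(list(r1 = width / 2, r2 = height / 2), class = "body_rect")
}

#' @param name One of `"face"` (25 cm x 25 cm) or `"torso"`
#'   (50 cm x 50 cm).
#' @rdname body_rect
#' @export
body_part <- function(name = c("face", "torso")) {
  name <- match.arg(name)
  switch(name, face = body_rect(25, 25), torso = body_rect(50, 50))
}

#' @export
print.body_rect <- function(x, ...) {
  cat(sprintf("<body_rect> %g cm x %g cm (half-extents r1 = %g, r2 = %g)\n",
              2 * x$r1, 2 * x$r2, x$r1, x$r2))
  invisible(x)
}
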