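#' PPS boundary by the detection-threshold rule
#'
#' The boundary of peripersonal space is operationalised as the farthest
#' swept distance at which the mean optimal prediction exceeds the
#' threshold (default 0.01).  On a monotone decreasing curve this
#' coincides with the first distance above threshold when scanning from
#' far to near.
#'
#' @param curve A `pps_curve` from [run_sweep()], or a data frame with
#'   columns `distance` and `mean`.
#' @param threshold Detection threshold on the mean prediction.
#' @return The boundary distance (cm).  Returns `NA` with a warning when
#'   no distance exceeds the threshold ("no boundary"); warns when every
#'   distance exceeds it (the grid is likely too short) and returns the
#'   largest swept distance.
#' @examples
#' curve <- data.frame(distance = 0:60,
#'                     mean = ifelse(0:60 <= 40, 1, 0))
#' boundary_threshold(curve)   # 40
#' @export
boundary_threshold <- function(curve, threshold = 0.01) {
  s <- .curve_summary(curve)
  above <- which(s$mean > threshold)
  if (length(above) == 0L) {
    warning("mean prediction never exceeds the threshold; no boundary",
            call. = FALSE)
    return(NA_real_)
  }
  if (length(above) == nrow(s)) {
    warning("mean prediction exceeds the threshold at every distance; ",
            "the swept grid may be too short", call. = FALSE)
  }
  s$distance[max(above)]
}

#' PPS boundary as the midpoint of a fitted sigmoid
#'
#' Fits a logistic `y(d) = A / (1 + exp(k * (d - d0)))` to the mean
#' prediction curve by Levenberg-Marquardt least squares and returns the
#' midpoint `d0` as the boundary.  The amplitude `A` is free (3D curves
#' can saturate below 1) and the lower asymptote is fixed at 0, the
#' model's far-field prediction.  Start values come from the curve's
#' half-maximum crossing.
#'
#' @inheritParams boundary_threshold
#' @return A list of class `pps_boundary` with `method`, `boundary`
#'   (= `d0`, cm), `amplitude`, `steepness` (`k`, 1/cm) and
#'   `resid_norm`.  Degenerate (near-constant) curves and non-convergent
#'   fits raise an error rather than returning a value.
#' @examples
#' d <- 0:100
#' exact <- data.frame(distance = d, mean = 1 / (1 + exp(0.3 * (d - 35))))
#' boundary_sigmoid(exact)$boundary   # 35
#' @export
boundary_sigmoid <- function(curve) {
  s <- .curve_summary(curve)
  y <- s$mean
  d <- s$distance
  if (diff(range(y)) < 1e-6) {
    stop("mean curve is (nearly) constant; sigmoid fit is degenerate",
         call. = FALSE)
  }
  half <- (min(y) + max(y)) / 2
  d0_start <- d[which.min(abs(y - half))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A / (1 + exp(k * (d - d0))),
      data = data.frame(d = d, y = y),
      start = list(A = max(y), k = 0.25, d0 = d0_start),
      lower = c(A = 1e-6, k = 1e-6, d0 = min(d) - diff(range(d))),
      upper = c(A = 1.5, k = 10, d0 = max(d) + diff(range(d))),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("sigmoid fit failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  est <- stats::coef(fit)
  structure(
    list(method = "sigmoid_midpoint",
         boundary = unname(est["d0"]),
         amplitude = unname(est["A"]),
         steepness = unname(est["k"]),
         resid_norm = sqrt(sum(stats::resid(fit)^2))),
    class = "pps_boundary"
  )
}

#' @export
print.pps_boundary <- function(x, ...) {
  cat(sprintf("<pps_boundary> %s: %.2f cm", x$method, x$boundary))
  if (!is.null(x$amplitude)) {
    cat(sprintf(" (A = %.3f, k = %.3f, resid = %.3g)",
                x$amplitude, x$steepness, x$resid_norm))
  }
  cat("\n")
  invisible(x)
}

#' Absolute slope of the prediction curve at its central value
#'
#' Locates the distance where the mean prediction is closest to the
#' midpoint between its minimum and maximum and returns the absolute
#' finite-difference gradient there (central difference on the distance
#' grid; one-sided at the grid ends).  For a logistic curve with
#' amplitude `A` and steepness `k`, the central slope is `A * k / 4`.
#'
#' @inheritParams boundary_threshold
#' @return Absolute slope (1/cm) at the curve's central value.
#' @examples
#' ramp <- data.frame(distance = 0:100, mean = seq(1, 0, length.out = 101))
#' boundary_slope(ramp)   # 0.01
#' @export
boundary_slope <- function(curve) {
  s <- .curve_summary(curve)
  y <- s$mean
  d <- s$distance
  if (length(y) < 2L || diff(range(y)) < 1e-12) {
    stop("slope is undefined for a constant curve", call. = FALSE)
  }
  i <- which.min(abs(y - (min(y) + max(y)) / 2))
  n <- length(y)
  lo <- max(1L, i - 1L)
  hi <- min(n, i + 1L)
  abs((y[hi] - y[lo]) / (d[hi] - d[lo]))
}

#' Boundary size and slope over a parameter grid
#'
#' Runs one distance sweep per row of the parameter grid (velocity
#' uncertainty, false-negative factor, prediction horizon) and tabulates
#' the threshold-rule boundary and the absolute central slope of each
#' mean curve.  The position uncertainty defaults to 0 so that the
#' boundary modulation is attributable to the swept parameters alone.
#'
#' @param sigma_v,fn,delta_t Numeric vectors; their values are crossed
#'   with [expand.grid()] unless `cross = FALSE`, in which case they are
#'   recycled to a common length and taken row-wise.
#' @param sigma_x Position uncertainty used for every grid point.
#' @param v True velocity (cm/s).
#' @param distances Distance grid for each sweep.
#' @param n_reps Repetitions per distance.
#' @param seed Optional seed applied once before the whole surface run.
#' @param cross Cross the parameter vectors (default) or zip them.
#' @return A data frame with columns `sigma_v`, `fn`, `delta_t`,
#'   `boundary` (cm) and `slope` (1/cm).
#' @examples
#' size_and_slope_surface(sigma_v = c(5, 20), fn = 5, delta_t = 0.5,
#'                        n_reps = 100, seed = 1)
#' @export
size_and_slope_surface <- function(sigma_v = c(5, 20, 35), fn = 5,
                                   delta_t = 0.5, sigma_x = 0, v = -25,
                                   distances = 0:150, n_reps = 1000L,
                                   seed = NULL, cross = TRUE) {
  grid <- if (cross) {
    expand.grid(sigma_v = sigma_v, fn = fn, delta_t = delta_t)
  } else {
    len <- max(length(sigma_v), length(fn), length(delta_t))
    data.frame(sigma_v = rep_len(sigma_v, len), fn = rep_len(fn, len),
               delta_t = rep_len(delta_t, len))
  }
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- sweep_config(
      distances, v = v,
      params = pps_params(sigma_x = sigma_x, sigma_v = grid$sigma_v[i],
                          fn = grid$fn[i], delta_t = grid$delta_t[i]),
      n_reps = n_reps
    )
    curve <- run_sweep(cfg)
    c(boundary = boundary_threshold(curve), slope = boundary_slope(curve))
  })
  cbind(grid, do.call(rbind, res))
}

# Accept either a pps_curve or a bare summary data frame.
.curve_summary <- function(curve) {
  if (inherits(curve, "pps_curve")) {
    s <- curve$summary
  } else if (is.data.frame(curve)) {
    s <- curve
  } else {
    stop("`curve` must be a pps_curve or a data frame", call. = FALSE)
  }
  if (!all(c("distance", "mean") %in% names(s)) || nrow(s) == 0L) {
    stop("curve must contain non-empty `distance` and `mean` columns",
         call. = FALSE)
  }
  s
}
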