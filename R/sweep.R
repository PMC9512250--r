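#' Configuration of a distance-sweep simulation
#'
#' A sweep evaluates the impact-prediction pipeline at each distance of a
#' grid, repeating the stochastic draw `n_reps` times per distance.
#' Predictions depend only on the current position and velocity, never on
#' the preceding trajectory, so distances are simulated independently.
#'
#' @param distances Strictly increasing grid of true distances (cm, >= 0).
#' @param v True velocity: a scalar for the 1D model or a 3-vector for the
#'   3D model (cm/s; negative axis-1 component = looming).
#' @param params A [pps_params()] or [pps_params_3d()] object.
#' @param body A [body_rect()]; required with 3D parameters, must be
#'   `NULL` otherwise.
#' @param n_reps Repetitions per distance (default 1000).
#' @param seed Optional integer seed; when supplied, [run_sweep()] is
#'   reproducible bit-for-bit.
#' @param label Optional condition label carried into outputs.
#' @return An object of class `sweep_config`.
#' @examples
#' sweep_config(0:100, v = -25, params = pps_params(), n_reps = 100)
#' @export
sweep_config <- function(distances, v, params, body = NULL,
                         n_reps = 1000L, seed = NULL, label = NULL) {
  stopifnot(is.numeric(distances), length(distances) >= 1L,
            all(distances >= 0), all(diff(distances) > 0),
            is.numeric(n_reps), n_reps >= 1)
  is3d <- inherits(params, "pps_params_3d")
  if (!is3d && !inherits(params, "pps_params")) {
    stop("`params` must be a pps_params or pps_params_3d object",
         call. = FALSE)
  }
  if (is3d) {
    if (is.null(body)) stop("3D sweeps require a `body` rectangle",
                            call. = FALSE)
    stopifnot(inherits(body, "body_rect"), is.numeric(v), length(v) == 3L)
  } else {
    if (!is.null(body)) stop("`body` is only meaningful for 3D sweeps",
                             call. = FALSE)
    stopifnot(is.numeric(v), length(v) == 1L)
  }
  structure(
    list(distances = as.numeric(distances), v = as.numeric(v),
         params = params, body = body, n_reps = as.integer(n_reps),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         label = label),
    class = "sweep_config"
  )
}

#' @export
print.sweep_config <- function(x, ...) {
  kind <- if (inherits(x$params, "pps_params_3d")) "3D" else "1D"
  cat(sprintf("<sweep_config> %s, %d distances in [%g, %g] cm, %d reps%s\n",
              kind, length(x$distances), min(x$distances), max(x$distances),
              x$n_reps,
              if (is.null(x$label)) "" else paste0(", label = ", x$label)))
  invisible(x)
}

#' Run a distance-sweep simulation
#'
#' For each distance, draws `n_reps` independent optimal predictions from
#' the full pipeline and summarises them by their mean and 25th/75th
#' percentiles (linear interpolation between order statistics).
#'
#' @param config A [sweep_config()].
#' @return An object of class `pps_curve`: a list with the per-distance
#'   sample matrix `samples` (`n_reps` rows, one column per distance), a
#'   `summary` data frame (`distance`, `mean`, `q25`, `q75`) and the
#'   originating `config`.
#' @examples
#' cfg <- sweep_config(seq(0, 100, 10), v = -25, params = pps_params(),
#'                     n_reps = 50, seed = 1)
#' curve <- run_sweep(cfg)
#' head(curve$summary)
#' @export
run_sweep <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  is3d <- inherits(config$params, "pps_params_3d")
  samples <- vapply(config$distances, function(d) {
    if (is3d) {
      predict_impact_3d(c(d, 0, 0), config$v, config$body, config$params,
                        n = config$n_reps)
    } else {
      predict_impact(d, config$v, config$params, n = config$n_reps)
    }
  }, numeric(config$n_reps))
  samples <- matrix(samples, nrow = config$n_reps,
                    dimnames = list(NULL, config$distances))
  summary <- data.frame(
    distance = config$distances,
    mean = unname(colMeans(samples)),
    q25 = apply(samples, 2, stats::quantile, probs = 0.25, names = FALSE),
    q75 = apply(samples, 2, stats::quantile, probs = 0.75, names = FALSE),
    row.names = NULL
  )
  structure(list(samples = samples, summary = summary, config = config),
            class = "pps_curve")
}

#' @export
print.pps_curve <- function(x, ...) {
  cat(sprintf("<pps_curve> %d distances x %d reps%s\n",
              ncol(x$samples), nrow(x$samples),
              if (is.null(x$config$label)) ""
              else paste0(" (", x$config$label, ")")))
  utils::str(x$summary, give.attr = FALSE)
  invisible(x)
}

#' Plot a prediction curve
#'
#' Diagnostic plot of the mean optimal prediction against distance with
#' the 25th/75th percentile band.
#'
#' @param x A `pps_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pps_curve <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$distance, s$mean, type = "l", ylim = c(0, 1),
                 xlab = "distance from body (cm)",
                 ylab = "optimal impact prediction y*", ...)
  graphics::points(s$distance, s$q25, pch = 3, cex = 0.5)
  graphics::points(s$distance, s$q75, pch = 3, cex = 0.5)
  invisible(x)
}

#' Within-condition variability profile of a prediction curve
#'
#' The interquartile range (q75 - q25) of the per-distance prediction
#' samples, together with the distance at which it peaks.  Impact
#' predictions are most variable near the graded PPS boundary, so the
#' peak localises the transition region.
#'
#' @param curve A `pps_curve` with at least 2 repetitions per distance.
#' @return A list with `profile` (data frame `distance`, `iqr`) and
#'   `peak_distance` (distance of the maximal IQR; first on ties).
#' @export
variability_profile <- function(curve) {
  stopifnot(inherits(curve, "pps_curve"))
  if (nrow(curve$samples) < 2L) {
    stop("variability is undefined for single-repetition curves",
         call. = FALSE)
  }
  iqr <- curve$summary$q75 - curve$summary$q25
  list(profile = data.frame(distance = curve$summary$distance, iqr = iqr),
       peak_distance = curve$summary$distance[which.max(iqr)])
}
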