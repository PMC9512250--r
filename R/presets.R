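#' Simulation presets for the published experiment conditions
#'
#' Returns ready-made [sweep_config()] objects for the distance-sweep
#' experiments the model was characterised with: the baseline curve
#' (`"fig2"`), velocity-uncertainty and false-negative sweeps (`"fig4a"`,
#' `"fig4b"`), the two looming speeds (`"fig5"`), looming vs receding
#' crossed with velocity uncertainty (`"fig6"`), the 3D face/torso grids
#' (`"fig8"`), the body-part-specific prediction horizons (`"fig9_left"`,
#' `"fig9_right"`), the sensitivity-surface grid (`"s6"`), and the
#' prediction-horizon sweep (`"s7"`).  Unlisted parameters are always the
#' baseline set.  Distance grids run in 1 cm steps from 0 to 100 cm, or to
#' 120 cm (150 cm for the longest horizon) where the boundary would
#' otherwise leave the grid.
#'
#' @param name Preset name (see above).
#' @param unbiased When `TRUE`, uses the unbiased loss `FN = FP = 1`
#'   instead of the baseline `FN = 5, FP = 1` (the "twin" variants of
#'   each experiment).
#' @param n_reps Optional override of the preset's repetitions per
#'   distance.
#' @param seed Optional seed stored in each config.
#' @return A single `sweep_config` (`"fig2"`) or a named list of them.
#' @examples
#' pps_preset("fig2")
#' names(pps_preset("fig4a", n_reps = 100))
#' @export
pps_preset <- function(name = c("fig2", "fig4a", "fig4b", "fig5", "fig6",
                                "fig8", "fig9_left", "fig9_right",
                                "s6", "s7"),
                       unbiased = FALSE, n_reps = NULL, seed = NULL) {
  name <- match.arg(name)
  fn <- if (unbiased) 1 else 5
  reps <- function(default) if (is.null(n_reps)) default else n_reps
  p1 <- function(...) pps_params(fn = fn, ...)
  d100 <- 0:100
  d120 <- 0:120

  cfgs <- switch(
    name,
    fig2 = sweep_config(d100, v = -25,
                        params = p1(grid_step = 0.001),
                        n_reps = reps(20), seed = seed, label = "baseline"),
    fig4a = {
      out <- lapply(c(5, 20, 35), function(sv) {
        sweep_config(d100, v = -25, params = p1(sigma_v = sv),
                     n_reps = reps(1000), seed = seed,
                     label = sprintf("sigma_v=%g", sv))
      })
      names(out) <- paste0("sigma_v_", c(5, 20, 35))
      out
    },
    fig4b = {
      out <- lapply(c(1, 5, 100), function(f) {
        sweep_config(d100, v = -25, params = pps_params(fn = f),
                     n_reps = reps(1000), seed = seed,
                     label = sprintf("FN=%g", f))
      })
      names(out) <- paste0("fn_", c(1, 5, 100))
      out
    },
    fig5 = {
      out <- lapply(c(-25, -75), function(v) {
        sweep_config(d120, v = v, params = p1(),
                     n_reps = reps(1000), seed = seed,
                     label = sprintf("v=%g", v))
      })
      names(out) <- c("v_m25", "v_m75")
      out
    },
    fig6 = {
      grid <- expand.grid(v = c(-12.5, 12.5, -25, 25),
                          sigma_v = c(5, 20, 35))
      out <- Map(function(v, sv) {
        sweep_config(d100, v = v, params = p1(sigma_v = sv),
                     n_reps = reps(1000), seed = seed,
                     label = sprintf("v=%g,sigma_v=%g", v, sv))
      }, grid$v, grid$sigma_v)
      names(out) <- sprintf("v_%s_sigma_v_%g",
                            sub("-", "m", grid$v), grid$sigma_v)
      out
    },
    fig8 = {
      grid <- expand.grid(body = c("face", "torso"),
                          sv1 = c(20, 30), sx_lat = c(5, 10),
                          sv_lat = c(5, 40), stringsAsFactors = FALSE)
      out <- Map(function(bp, sv1, sx, sv) {
        sweep_config(
          d120, v = c(-25, 0, 0),
          params = pps_params_3d(sigma_x = c(2.5, sx, sx),
                                 sigma_v = c(sv1, sv, sv), fn = fn),
          body = body_part(bp), n_reps = reps(1000), seed = seed,
          label = sprintf("%s,sv1=%g,sx23=%g,sv23=%g", bp, sv1, sx, sv))
      }, grid$body, grid$sv1, grid$sx_lat, grid$sv_lat)
      names(out) <- sprintf("%s_sv1_%g_sx_%g_sv_%g",
                            grid$body, grid$sv1, grid$sx_lat, grid$sv_lat)
      out
    },
    fig9_left = ,
    fig9_right = {
      dt_torso <- if (name == "fig9_right") 0.75 else 0.5
      out <- list(
        face = sweep_config(
          d120, v = c(-25, 0, 0),
          params = pps_params_3d(sigma_x = c(2.5, 5, 5),
                                 sigma_v = c(20, 5, 5), fn = fn,
                                 delta_t = 0.5),
          body = body_part("face"), n_reps = reps(1000), seed = seed,
          label = "face,dT=0.5"),
        torso = sweep_config(
          d120, v = c(-25, 0, 0),
          params = pps_params_3d(sigma_x = c(2.5, 5, 5),
                                 sigma_v = c(20, 5, 5), fn = fn,
                                 delta_t = dt_torso),
          body = body_part("torso"), n_reps = reps(1000), seed = seed,
          label = sprintf("torso,dT=%g", dt_torso))
      )
      out
    },
    s6 = {
      grid <- expand.grid(sigma_v = c(5, 20, 35), fn_s6 = c(1, 5, 100),
                          delta_t = c(0.25, 0.5, 1))
      out <- Map(function(sv, f, dt) {
        sweep_config(0:150, v = -25,
                     params = pps_params(sigma_x = 0, sigma_v = sv,
                                         fn = f, delta_t = dt),
                     n_reps = reps(1000), seed = seed,
                     label = sprintf("sigma_v=%g,FN=%g,dT=%g", sv, f, dt))
      }, grid$sigma_v, grid$fn_s6, grid$delta_t)
      names(out) <- sprintf("sigma_v_%g_fn_%g_dt_%g",
                            grid$sigma_v, grid$fn_s6, grid$delta_t)
      out
    },
    s7 = {
      out <- lapply(c(0.25, 0.5, 1), function(dt) {
        sweep_config(0:150, v = -25, params = p1(delta_t = dt),
                     n_reps = reps(1000), seed = seed,
                     label = sprintf("dT=%g", dt))
      })
      names(out) <- paste0("dt_", c(0.25, 0.5, 1))
      out
    }
  )
  cfgs
}
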