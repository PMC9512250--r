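test_that("3D percept sampling is per-axis with an axis-1 clamp only", {
  prm0 <- pps_params_3d(sigma_x = c(0, 0, 0), sigma_v = c(0, 0, 0))
  p <- sample_percept_3d(c(30, 2, -3), c(-25, 1, 4), prm0)
  expect_equal(drop(p$x_hat), c(30, 2, -3))
  expect_equal(drop(p$v_hat), c(-25, 1, 4))

  set.seed(201)
  prm <- pps_params_3d(sigma_x = c(5, 5, 5), sigma_v = c(10, 10, 10))
  p <- sample_percept_3d(c(0, 0, 0), c(-25, 0, 0), prm, n = 5000)
  # negative depth samples are clamped to just in front of the body ...
  expect_true(all(p$x_hat[, 1] > 0))
  expect_gt(mean(p$x_hat[, 1] == 0.1), 0.4)
  # ... while lateral samples may be negative
  expect_lt(min(p$x_hat[, 2]), 0)
  expect_lt(min(p$x_hat[, 3]), 0)
  # per-axis means recover the truth within Monte-Carlo tolerance
  expect_lt(abs(mean(p$x_hat[, 2])), 3 * 5 / sqrt(5000))
  expect_lt(abs(mean(p$v_hat[, 1]) + 25), 3 * 10 / sqrt(5000))
})

test_that("hit test implements the line-of-sight crossing geometry", {
  face <- body_part("face")  # half-extents 12.5 x 12.5

  # head-on trajectory crosses the plane at the origin
  expect_true(hit_test(c(-1, 0, 0), c(10, 0, 0), face))
  # a future point in front of the body is never a hit
  expect_false(hit_test(c(1, 0, 0), c(10, 0, 0), face))

  # crossing ordinate exactly at the rectangle edge vs just outside:
  # percept at (10, 0, 0), future at (-10, c2 * 2, 0) crosses at t = 0.5
  # with ordinate c2
  at_edge <- c(-10, 12.5 * 2, 0)
  outside <- c(-10, (12.5 + 1e-6) * 2, 0)
  expect_true(hit_test(at_edge, c(10, 0, 0), face))
  expect_false(hit_test(outside, c(10, 0, 0), face))

  # vertical extent uses r2
  expect_true(hit_test(c(-10, 0, 12.5 * 2), c(10, 0, 0), face))
  expect_false(hit_test(c(-10, 0, (12.5 + 1e-6) * 2), c(10, 0, 0), face))

  # a percept at or behind the plane is undefined geometry
  expect_error(hit_test(c(-1, 0, 0), c(0, 0, 0), face), "in front")

  # vectorised over rows
  f <- rbind(c(-1, 0, 0), c(1, 0, 0), c(-10, 50, 0))
  expect_equal(hit_test(f, c(10, 0, 0), face), c(TRUE, FALSE, FALSE))
})

test_that("Monte-Carlo hit probability reduces to 1D with no lateral noise", {
  prm <- pps_params_3d(sigma_x = c(2.5, 0, 0), sigma_v = c(20, 0, 0),
                       n_mc = 10000)
  p1d <- hit_probability(30 + 0.5 * -25,
                         sqrt(2.5^2 + (0.5 * 20)^2))
  set.seed(202)
  p3d <- hit_probability_3d(c(30, 0, 0), c(-25, 0, 0), body_part("face"),
                            prm)
  # 99% binomial Monte-Carlo bound at n_mc = 10000
  expect_lt(abs(p3d - p1d), 2.58 * sqrt(p1d * (1 - p1d) / 10000))

  # an effectively infinite rectangle cannot be missed even with large
  # lateral noise
  prm_lat <- pps_params_3d(sigma_x = c(2.5, 10, 10),
                           sigma_v = c(20, 40, 40), n_mc = 10000)
  set.seed(203)
  p_inf <- hit_probability_3d(c(30, 0, 0), c(-25, 0, 0),
                              body_rect(2e6, 2e6), prm_lat)
  expect_lt(abs(p_inf - p1d), 2.58 * sqrt(p1d * (1 - p1d) / 10000))

  # a vanishing rectangle is a measure-zero target
  set.seed(204)
  p_zero <- hit_probability_3d(c(30, 0, 0), c(-25, 0, 0),
                               body_rect(1e-9, 1e-9), prm_lat)
  expect_equal(p_zero, 0)
})

test_that("Monte-Carlo estimate agrees with deterministic quadrature", {
  body <- body_part("face")
  configs <- list(
    list(x_hat = c(20, 0, 0), v_hat = c(-30, 0, 0),
         sx = c(2.5, 5, 5), sv = c(20, 10, 10)),
    list(x_hat = c(8, 4, -2), v_hat = c(-25, 5, 0),
         sx = c(2, 8, 8), sv = c(15, 30, 30)),
    list(x_hat = c(40, -10, 5), v_hat = c(-60, 0, 10),
         sx = c(5, 5, 5), sv = c(25, 40, 40))
  )
  for (cfg in configs) {
    prm <- pps_params_3d(sigma_x = cfg$sx, sigma_v = cfg$sv, n_mc = 1e6)
    mu <- cfg$x_hat + 0.5 * cfg$v_hat
    sig <- sqrt(cfg$sx^2 + (0.5 * cfg$sv)^2)
    exact <- quadrature_hit_probability(cfg$x_hat, mu, sig, body)
    set.seed(205)
    mc <- hit_probability_3d(cfg$x_hat, cfg$v_hat, body, prm)
    expect_lt(abs(mc - exact),
              3 * sqrt(max(exact * (1 - exact), 1e-8) / 1e6) + 1e-4)
  }
})

test_that("hit probability is nondecreasing in the body-part size", {
  prm <- pps_params_3d(sigma_x = c(2.5, 8, 8), sigma_v = c(20, 30, 30),
                       n_mc = 20000)
  sizes <- c(5, 10, 25, 50, 100)
  # common random numbers: the same future samples are tested against a
  # growing rectangle, so the hit set grows monotonically
  probs <- vapply(sizes, function(s) {
    set.seed(206)
    hit_probability_3d(c(15, 0, 0), c(-25, 0, 0), body_rect(s, s), prm)
  }, numeric(1))
  expect_true(all(diff(probs) >= 0))
  probs_r2 <- vapply(sizes, function(s) {
    set.seed(206)
    hit_probability_3d(c(15, 0, 0), c(-25, 0, 0), body_rect(25, s), prm)
  }, numeric(1))
  expect_true(all(diff(probs_r2) >= 0))
})

test_that("3D pipeline: sure hits, 1D equivalence, lateral-noise damping", {
  noiseless <- pps_params_3d(sigma_x = c(0, 0, 0), sigma_v = c(0, 0, 0),
                             n_mc = 1000)
  expect_equal(predict_impact_3d(c(5, 0, 0), c(-25, 0, 0),
                                 body_part("face"), noiseless), 1)
  # noiseless receding object: no contact predicted
  expect_equal(predict_impact_3d(c(50, 0, 0), c(25, 0, 0),
                                 body_part("face"), noiseless), 0)

  # with lateral SDs at 0 the prediction distribution matches the 1D model
  prm3 <- pps_params_3d(sigma_x = c(2.5, 0, 0), sigma_v = c(20, 0, 0),
                        n_mc = 2000)
  set.seed(207)
  y3 <- predict_impact_3d(c(30, 0, 0), c(-25, 0, 0), body_part("face"),
                          prm3, n = 1500)
  y1 <- predict_impact(30, -25, pps_params(), n = 1500)
  se <- sqrt(stats::var(y3) / 1500 + stats::var(y1) / 1500)
  expect_lt(abs(mean(y3) - mean(y1)), 3 * se + 0.01)

  # increasing lateral position noise cannot increase the mean prediction
  mean_at_lat_sd <- function(sx_lat) {
    prm <- pps_params_3d(sigma_x = c(2.5, sx_lat, sx_lat),
                         sigma_v = c(20, 10, 10), n_mc = 2000)
    set.seed(208)
    mean(predict_impact_3d(c(10, 0, 0), c(-25, 0, 0), body_part("face"),
                           prm, n = 400))
  }
  m <- vapply(c(0, 5, 15, 40), mean_at_lat_sd, numeric(1))
  expect_true(all(diff(m) <= 0.02))
})

test_that("scalar and batched Monte-Carlo paths agree distributionally", {
  prm <- pps_params_3d(sigma_x = c(2.5, 5, 5), sigma_v = c(20, 20, 20),
                       n_mc = 4000)
  body <- body_part("face")
  set.seed(209)
  batch <- predict_impact_3d(c(20, 0, 0), c(-25, 0, 0), body, prm, n = 300)
  scalar <- replicate(300, {
    p <- sample_percept_3d(c(20, 0, 0), c(-25, 0, 0), prm)
    ph <- hit_probability_3d(drop(p$x_hat), drop(p$v_hat), body, prm)
    optimal_prediction(ph, prm)
  })
  se <- sqrt(stats::var(batch) / 300 + stats::var(scalar) / 300)
  expect_lt(abs(mean(batch) - mean(scalar)), 3 * se + 0.01)
})
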