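# Independent oracles used to validate the model's closed-form and
# Monte-Carlo computations.  These never call the implementation paths
# they check.

# Gaussian lower-tail mass at 0 by trapezoidal integration of the density.
trapezoid_tail_mass <- function(mu, sigma, n = 200000L) {
  lo <- mu - 12 * sigma
  x <- seq(lo, 0, length.out = n)
  dens <- exp(-0.5 * ((x - mu) / sigma)^2) / (sigma * sqrt(2 * pi))
  sum((dens[-1] + dens[-n]) / 2) * (x[2] - x[1])
}

# Exhaustive fine-grid argmin of the expected quadratic loss.
brute_force_argmin <- function(p, fn, fp, step = 1e-4) {
  grid <- seq(0, 1, by = step)
  el <- p * fn * (1 - grid)^2 + (1 - p) * fp * grid^2
  grid[which.min(el)]
}

# Deterministic 3D crossing probability.  Conditional on the axis-1
# future position f1 <= 0, the crossing ordinate along lateral axis j is
# linear in f_j, so the lateral hit condition is an interval in f_j and
# the triple integral reduces to a 1D integral over f1.
quadrature_hit_probability <- function(percept, mu, sigma, body) {
  lateral_mass <- function(f1, j, r) {
    t <- percept[1] / (percept[1] - f1)
    lo <- percept[j] + (-r - percept[j]) / t
    hi <- percept[j] + (r - percept[j]) / t
    if (sigma[j] == 0) {
      as.numeric(mu[j] >= lo & mu[j] <= hi)
    } else {
      pnorm(hi, mu[j], sigma[j]) - pnorm(lo, mu[j], sigma[j])
    }
  }
  integrand <- function(f1) {
    dnorm(f1, mu[1], sigma[1]) *
      lateral_mass(f1, 2, body$r1) * lateral_mass(f1, 3, body$r2)
  }
  stats::integrate(integrand, lower = mu[1] - 12 * sigma[1], upper = 0,
                   rel.tol = 1e-10, subdivisions = 500L)$value
}

baseline_params <- function(...) pps_params(...)
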