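---
title: "A Bayesian impact-prediction account of peripersonal space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian impact-prediction account of peripersonal space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppsimpact)
```

## The model

Peripersonal space (PPS) is the graded zone around the body in which
multisensory neurons respond to nearby visual or auditory stimuli.
`ppsimpact` simulates an ideal observer for whom PPS encoding *is*
contact prediction: at time $T$ an object at distance $x_T$ (cm, body
surface at 0) moves with velocity $v_T$ (cm/s, negative = looming), and
the observer predicts whether the object will touch the body at or
before $T + \Delta T$.

The pipeline has four stages.

1. **Perception with noise.** The observer receives point estimates
   $\hat{x}_T \sim N(x_T, \sigma_x)$ and $\hat{v}_T \sim N(v_T,
   \sigma_v)$, drawn independently.  A raw position sample inside the
   body ($\hat{x}_T < 0$) is replaced by $0.1$ cm — the observer's
   position estimate is restricted to the space in front of the body.
   The clamp applies to the point estimate only; the encoded
   distribution is not truncated (the natural reading of the estimation
   procedure, and the simpler rule).  Velocity samples are never
   clamped.
2. **Future-position belief.** Estimates are encoded together with
   their uncertainty, so the believed future position is
   $\hat{X}_{T+\Delta T} \sim N\!\left(\hat{x}_T + \Delta T \hat{v}_T,\;
   \sqrt{\sigma_x^2 + (\Delta T \sigma_v)^2}\right)$.
   Velocity is assumed constant within $\Delta T$.  Note that
   $\sigma_x$ and $\sigma_v$ enter only through the combined SD, so
   manipulating one is interchangeable with manipulating the other up
   to the factor $\Delta T$.
3. **Hit probability.** Contact ($y = 1$) occurs when the future
   position is at or behind the body surface, so
   $P(y = 1) = P(\hat{X}_{T+\Delta T} \le 0)$.  In 1D this is the
   Gaussian tail mass `pnorm(0, mu, sigma)`, evaluated in closed form
   for exactness and speed; the degenerate noiseless case
   $\sigma = 0$ is the pointwise limit, a step function at 0.
4. **Bayesian decision.** The graded prediction
   $y^*_{\text{pred}} \in [0, 1]$ minimises the expected loss under the
   asymmetric loss
   $\mathrm{loss}(y, y_{\text{pred}}) =
   FP\,\max(0, y_{\text{pred}} - y)^r + FN\,\max(0, y - y_{\text{pred}})^r$,
   with $r = 2$ throughout.  $FN > FP$ encodes the precautionary
   principle — failing to predict a real impact is costlier than a
   false alarm.  The minimisation is performed on the candidate grid
   $\{0, 0.05, \dots, 1\}$ (the convention of the original simulation
   experiments); for $r = 2$ the analytic minimiser
   $p\,FN / (p\,FN + (1 - p)\,FP)$ is exposed as
   `optimal_prediction_cf()` and serves as an oracle in the test suite.
   Grid ties are broken toward the smaller candidate; this can only
   matter for degenerate loss configurations that the parameter
   constructors reject ($FN + FP > 0$).

With $FP = FN$ the optimal prediction equals the hit probability
itself; with zero perceptual noise the prediction for a receding object
is exactly 0.  Both limits are enforced as tests.

## Default parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `sigma_x` | 2.5 | cm | position-estimation noise SD |
| `sigma_v` | 20 | cm/s | velocity-estimation noise SD |
| `fn` | 5 | — | false-negative loss factor |
| `fp` | 1 | — | false-positive loss factor |
| `r` | 2 | — | loss exponent |
| `delta_t` | 0.5 | s | prediction horizon |
| `grid_step` | 0.05 | — | candidate-grid spacing |
| `n_mc` (3D) | 10000 | — | Monte-Carlo samples per hit probability |

The defaults are the baseline condition of the simulation experiments;
every preset varies one or two of them and keeps the rest.  $\Delta T$
is interpretable as the time needed to execute a defensive action, so
body parts that are slower to protect (the torso vs the face) plausibly
carry a larger horizon — the `fig9_right` preset implements exactly
that contrast (0.75 s vs 0.5 s).

## The 3D extension

Position and velocity become 3-vectors; axis 1 is depth toward the
body, axes 2/3 span the body-part *collision plane*, a rectangle of
half-extents $r_1, r_2$ centred on the origin (face $25 \times 25$ cm,
torso $50 \times 50$ cm; depth of the body part is ignored).  Each axis
is perceived independently, and the future position is a trivariate
normal with diagonal covariance.  Only the axis-1 position sample is
clamped: lateral clamping has no geometric justification.

A sampled future position counts as a hit when it lies behind the
collision plane *and* the straight segment from the perceived current
position $\hat{\mathbf{x}}_T$ to it crosses the plane inside the
rectangle.  The crossing point is linear in the future position, with
$t = p_1 / (p_1 - f_1)$, so the lateral hit condition is an interval in
each lateral coordinate whose bounds are linear in $f_1$.  The segment
deliberately starts at the *perceived* position, not the true one: the
observer can only reason from its own estimate.  The hit probability is
estimated as the fraction of `n_mc = 10000` Monte-Carlo samples of the
future position that pass this test; the decision stage is then shared
with the 1D model.  With zero lateral uncertainty and on-axis motion
the rectangle cannot be missed laterally and the model reduces exactly
to the 1D model — a property the tests check against the closed form.

The test suite also contains a deterministic oracle that integrates the
crossing probability exactly: conditional on $f_1$, the lateral hit
conditions factorise into two normal-interval masses, reducing the
triple integral to a 1D quadrature (`stats::integrate`).  Monte Carlo
remains the production path because it is what the simulation
experiments specify and it degrades gracefully when lateral
uncertainties are exactly zero.

In the vectorised sweep path, lateral components are drawn only for
samples already behind the plane; samples in front can never hit, so
the estimate's distribution is unchanged while most of the sampling
cost disappears.  The scalar reference path (`hit_probability_3d`)
draws all three axes for every sample; the two are compared
distributionally in the tests.

## Sweeps, presets and reproducibility

`run_sweep()` evaluates the pipeline at every distance of a grid
(`n_reps` independent draws per distance; fresh percept and fresh
Monte-Carlo samples per draw) and summarises each distance by the mean
and the 25th/75th percentiles (type-7 linear interpolation).
Predictions depend only on the current state, never on the previous
trajectory, so distances are independent.  A `seed` stored in the
config makes a sweep reproducible bit-for-bit; draws are consumed in
(position, velocity, future-position) order per distance.

The published experiment conditions are exposed as presets
(`pps_preset()`): the baseline curve (20 repetitions per distance,
grid step 0.001), the $\sigma_v$ and $FN$ sweeps, the two looming
speeds, looming vs receding at $\pm 12.5$ and $\pm 25$ cm/s, the 3D
face/torso grids, the body-part-specific horizons, and the
sensitivity-surface grid (with $\sigma_x = 0$ so the swept parameters
alone drive the modulation).  Every preset has an `unbiased = TRUE`
twin with $FN = FP = 1$.  Distance grids are not printed in the
original experiment descriptions; the presets use 1 cm steps from 0 to
100 cm, extended to 120 cm (150 cm for the longest horizons) where the
boundary would otherwise leave the grid — 1 cm resolution keeps the
boundary-location quantisation below the stochastic error at
`n_reps = 1000`.  The exact lateral-uncertainty combinations of the 3D
grid are likewise not printed exhaustively; the `fig8` preset crosses
$\sigma^{2,3}_x \in \{5, 10\}$ cm with $\sigma^{2,3}_v \in \{5, 40\}$
cm/s, which covers every combination the experiment text names.

## Boundary metrics

Two operationalisations of the PPS boundary are implemented.

* **Threshold rule** (`boundary_threshold()`): the farthest swept
  distance at which the mean prediction exceeds 0.01.  The rule is
  stated in the literature both as "the first value above 0.01"
  (scanning from far) and "the farthest distance above 0.01"; on a
  monotone decreasing curve these coincide, and the farthest-distance
  reading is the implemented one.  A curve that never exceeds the
  threshold yields `NA` ("no boundary"); a curve that always exceeds
  it returns the largest distance with a warning that the grid is
  likely too short.
* **Sigmoid midpoint** (`boundary_sigmoid()`): the midpoint $d_0$ of a
  logistic $A / (1 + e^{k (d - d_0)})$ fitted by Levenberg–Marquardt
  least squares.  The functional family is not fixed by convention
  ("a sigmoid function"); the logistic is chosen as the standard
  psychometric choice.  The amplitude is free because 3D curves can
  saturate well below 1 (the large-lateral-noise face condition peaks
  near 0.6), and the lower asymptote is fixed at 0, the model's
  far-field prediction.  Start values come from the half-maximum
  crossing; degenerate (near-constant) curves raise an error rather
  than returning a number.

`boundary_slope()` reports the absolute finite-difference gradient at
the distance where the mean is nearest to its central value (central
difference; one-sided at grid ends), and
`size_and_slope_surface()` tabulates boundary and slope over a
$\sigma_v \times FN \times \Delta T$ grid.

The two boundary notions react very differently to sensory
uncertainty, and this difference is itself a finding worth preserving:
under the unbiased loss the mean curve is (up to grid snapping) the
mean hit probability, whose half-maximum distance
$-\Delta T \, v_T$ is independent of $\sigma_v$, so the fitted
midpoint barely moves while the threshold rule tracks the flattening
tail outward by tens of cm.  The residual midpoint drift of a few cm
comes from fitting a logistic to a probit-shaped curve truncated at
$d = 0$; the tests operationalise "invariant" as a midpoint shift
below 6 cm and below 15% of the concurrent threshold-rule shift.

## Problem sizes and numerical choices

The stochastic experiment checks use 1000 repetitions per distance on
1 cm grids — the repetition count the experiments report — which makes
a 1D sweep essentially instantaneous and a full 3D sweep (121 distances
× 1000 repetitions × 10000 Monte-Carlo samples) a few minutes of
vectorised sampling.  Property-style tests use smaller draws (hundreds
of repetitions, thousands of Monte-Carlo samples) with explicit
binomial or 3-standard-error tolerances.  Monotonicity checks on
Monte-Carlo quantities use common random numbers (the same seed before
each call) so that the comparison is exact rather than statistical.

Known limitations: velocities are constant within the horizon; noise
is Gaussian and axis-independent; only a single rectangular,
axis-aligned body part is modelled; and the generator emulates the
simulation experiments, not empirical reaction-time data — passing
tests show that the normative model behaves as published, not that
human PPS measurements will match it quantitatively.
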