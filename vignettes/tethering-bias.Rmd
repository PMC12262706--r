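---
title: "When does condensate tethering matter? Models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{When does condensate tethering matter? Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetherSMT)
```

## The problem

Biomolecular condensates reconstituted in vitro are colloidal droplets:
unless anchored to the coverslip, the whole condensate translates and
rotates under thermal fluctuations. Single-molecule tracking (SMT) of guest
molecules inside such a droplet then reports the *sum* of intra-condensate
diffusion and whole-condensate motion, biasing apparent diffusion
coefficients (`D_app`), anomalous exponents (`alpha_app`) and step-size
distributions. tetherSMT simulates this situation with known ground truth
and quantifies the bias, so that an experimenter can decide — given the
condensate size and the mobility of the molecule of interest — whether
surface tethering is required.

## The simulation model

Guest molecules move by 2D fractional Brownian motion: each axis is an
independent FBM with Hurst exponent `H = alpha/2`, scaled so that the
ensemble MSD obeys `MSD(tau) = 4 D tau^alpha` (`tau` in seconds, `D` in
um^2/s^alpha). Increments are synthesised from the exact FGN covariance by
Cholesky factorisation (exact; cached per parameter set) or by circulant
embedding for long tracks. Defaults follow typical SMT settings: 50 ms
frames, 20 steps, 1000 molecules per condition, molecules initialised
uniformly in the axis-aligned square of side `diameter` (a disc-restricted
option exists).

Whole-condensate rotation is modelled per time step by one shared random
angle applied to all molecules about the condensate centre. The
characteristic rate comes from the Stokes–Einstein relation for a sphere,

    omega = kB T / (4 pi eta r^3),

with `T = 298` K, `eta = 5` mPa s (a ~10 mg/ml protein solution) and `r`
the condensate radius in metres. Condensate translation is deliberately not
simulated; rotation is the component that scales with the position inside
the condensate and produces the size-dependent bias studied here.

### Two conventions that matter

**Per-step angle distribution** (`theta_model`). The default, `"speed"`,
treats `omega` as a mean angular speed and draws
`theta ~ N(0, sd = omega * dt)`. The alternative `"diffusive"` treats it
as a planar rotational diffusivity, `theta ~ N(0, var = 2 omega dt)`.
These differ enormously in their size scaling (`omega^2` vs `omega`). Only
the `"speed"` convention reproduces the guideline this package is built to
test — condensates larger than ~2 um show no measurable bias while small
condensates bias slow molecules strongly; under the `"diffusive"`
convention even 5 um condensates would bias slow molecules by an order of
magnitude, which contradicts both that guideline and the small rotational
amplitudes observed experimentally for ~1 um tethered-free droplets over
10 s movies. We therefore default to `"speed"` and keep `"diffusive"` as a
switch (the rotation-physics tests exercise it, since its cumulative angle
variance has the simple closed form `2 omega dt k`).

**Rotation geometry** (`rotation_geometry`). The default,
`"small_angle"`, displaces each molecule by `theta` scaled by its distance
from the centre, perpendicular to its position vector — the first-order
scheme. Its rotational contribution is an i.i.d. Gaussian-like increment,
so it adds an effectively Brownian component: the apparent exponent of
free diffusion (`alpha = 1`) is untouched while `D_app` inflates, and for
confined molecules (`alpha = 0.5`) both `D_app` and `alpha_app` inflate.
The `"exact"` mode applies the exact rotation matrix instead; it preserves
distances to the centre to machine precision (the rigidity invariants in
the test suite use it) but saturates displacements once per-step angles
approach a radian — at the smallest diameters in the sweep (0.3 um,
`omega dt ~ 1` rad) it *deflates* the apparent exponent, which is why it
is not the default for bias studies. The small-angle scheme has the
complementary artifact: at per-step angles ~1 rad it inflates radii
exponentially, so `D_app` ratios at 0.3 um should be read as "very large"
rather than as calibrated numbers. Between 0.45 and 5 um — the range where
the guideline question is actually decided — the two geometries agree.

## The analysis pipeline

Per track, the time-averaged MSD is computed over all ordered sample pairs
at each integer frame lag (frame gaps respected, lags in true time). Two
fits follow, both over the first `max(floor(L/2), 4)` lags of a track of
`L` frames:

* log–log OLS `log MSD = alpha_app log tau + log(2 n D)` gives the
  apparent anomalous exponent; fits with `R^2 < 0.7` or `alpha_app <
  0.01` are flagged and excluded from exponent distributions;
* linear OLS through the motion-blur model
  `MSD = 2 n D tau + 2 sigma^2 - 4 D R tau` (tracking dimension `n = 2`,
  blur coefficient `R = 1/6` for continuous exposure) gives
  `D_app = 3 m / 10` from slope `m` and localization error
  `sigma = sqrt(b/2)` from intercept `b >= 0`; negative intercepts clamp
  `sigma` to 0 with a flag, non-positive slopes floor `D_app` at a small
  epsilon so log-scale summaries stay defined.

Even on noise-free tethered simulations the recovered mean exponent is a
few percent below truth (~0.95 for `alpha = 1` at 20 steps): a known
systematic of short-track time-averaged MSD fitting, not of the simulator.
The acceptance targets measure exactly this pipeline output.

Track filters mirror the experimental rules: the `ensemble_msd` profile
(length >= 10 frames, `log10 D_app` above a static-error threshold
`log10(sigma_static^2 / (2 dt))` from a 30 nm stationary calibration,
start-to-end displacement >= 0.2 um) and the `alpha` profile (mean step
>= 30 nm plus the fit-quality rules). For *simulated* sweeps the mobility
rules are deliberately not applied: zero-noise tracks at slow ground-truth
D would be wiped out wholesale (a 30 nm mean step corresponds to
`D ~ 6e-3` um^2/s at 50 ms), censoring precisely the slow-D region the
sweep exists to probe. `bias_ratio(profile = "sim")` therefore keeps only
the fit-quality rules; the experimental profiles remain available.

## Rotation-referenced kinematics

For each track the angle between the current and initial position vector
(relative to the condensate centre) is unwrapped into a time series;
angular velocity and acceleration are first differences. Scalar summaries
follow stated conventions, each with a raw switch, because the upstream
normalisations are not fixed by any published formula:

* velocity autocorrelation: mean of `g(tau)/Var(omega)` over lags 1..5
  (normalized; bounded, persistence-interpretable) or raw mean `g(tau)`.
  Note the raw form scales with angular-velocity *amplitude*; the ordering
  "untethered explores more than tethered" is a statement about that
  amplitude and holds for the raw form, whereas variance normalisation
  divides the amplitude signal away and can invert the ordering for
  strongly anti-persistent confined motion.
* velocity–acceleration correlation: Pearson correlation of aligned
  series (negative = damped/restrained, positive = driven). For reference,
  white-noise angular velocity gives -1/sqrt(2), not 0, against its own
  difference quotient.
* phase-space area: convex-hull area of the (omega, accel) cloud,
  rad^2/s^3.

Because every molecule in a condensate shares one rotation history, these
summaries are strongly correlated *within* a condensate; inferences should
pool several condensates (see below). Absolute experimental values of
these summaries are convention-dependent and are not reproduction targets;
orderings and effect directions are.

## The bias sweep and its scaled tests

`run_sweep()` samples `(log10 D, diameter)` by a 2D Sobol sequence
(defaults: 200 points over `D` in 0.001–1 um^2/s and diameters 0.3–5 um,
exponents 1.0 and 0.5) and simulates a tethered/untethered pair per point
with identical molecular noise, so the ratio of median apparent metrics
(untethered/tethered) isolates the rotation bias. `build_heatmap()` bins
points onto a regular grid (nearest assignment with explicit missing
cells, or inverse-distance interpolation); `guideline_check()` labels
cells unbiased within a 10% ratio tolerance and extracts the bias
frontier — per `D` row, the smallest diameter from which all larger
diameters are unbiased.

The test suite runs a scaled sweep (32 points, 200 tracks per condition)
with two design choices worth recording:

* **Condensate pooling.** Each condition's tracks are split over 4 (corner
  checks: 8–10) independent condensates. A single condensate contributes
  one rotation path, so per-condition exponent ratios from one condensate
  swing wildly across seeds; pooling restores the averaging that the
  dense 200-point production sweep achieves through cell aggregation and
  that experiments achieve by imaging many condensates.
* **Regular frontier grid.** Frontier monotonicity is asserted on a
  dedicated regular grid (3 `D` values x 5 diameters) rather than on the
  binned Sobol points: with 32 points, the smallest *sampled* diameter
  differs between `D` rows, which makes even the noise-free binned
  frontier non-monotone — a sampling artifact, not physics.

A green sweep test establishes the *direction and location* of the bias at
scaled resolution. It does not certify absolute ratio values at the 0.3 um
boundary (geometry-scheme artifacts dominate there, see above), nor
anything about condensate translation, boundary interactions or
photophysics, none of which are modelled.

## Synthetic experimental fixtures

`generate_fixture()` emulates four imaging regimes as spot tables with
known ground truth: microsphere tracers at 100 ms and 20 ms (100-frame
movies, `D = 0.001` um^2/s — tracers slow enough that condensate motion
dominates the untethered signal, 15 nm localization noise), structured
mRNA at 200 ms (`D = 0.004` um^2/s, `alpha = 0.8`, 30 nm noise) and
unstructured poly(U) RNA at 20 ms (`D = 0.5` um^2/s, `alpha = 0.85`,
30 nm noise). The RNA presets are *emulation presets* chosen to match the
observed order of magnitude of each regime (slow/confined vs fast with an
order-of-magnitude timescale separation), not ground truth of any
experiment. The generator adds i.i.d. Gaussian localization noise only: no
blinking, bleaching, detection misses, linking errors or depth effects, so
fixture-based tests validate the analysis arithmetic, not robustness to
real detection artifacts.

## Statistics

Group comparisons use the Mann–Whitney U test (exhaustive enumeration of
the rank assignment for combined n <= 20 — valid under ties — and the
tie-corrected normal approximation otherwise, continuity correction on by
default), Kruskal–Wallis for several groups, and Cliff's delta with the
conventional thresholds (|delta| < 0.147 negligible, < 0.33 small,
< 0.474 medium, else large; half-open). Figure annotations follow the
legend scheme in which a negligible effect size overrides any p value to
"ns". Raw p values are reported; no multiple-testing correction is
applied, deliberately.

## Circularity

Object circularity on segmentation masks is `4 pi A / P^2` with `A` the
pixel count and `P` the polygonal length of the marching-squares contour
at level 0.5 (raw pixel-edge counting systematically deflates
circularity). Values marginally above 1 from discretization are clipped
and flagged. ImageJ's estimator differs by a few percent; absolute values
are therefore comparable only within one estimator.

## Numerical notes and limitations

* All randomness flows from one master seed through counter-based child
  seeds (Lehmer mixing, < 2^31), making tethered/untethered pairing exact
  and order-independent; rotation draws live on a dedicated child stream
  so toggling rotation cannot perturb molecular noise.
* `alpha` is restricted to (0, 2); the FGN covariance embedding is invalid
  outside. `D = 0` is allowed as a degenerate frozen case.
* Zero-MSD lags are dropped before log fits; tracks with fewer than 4
  usable lags are failed, not guessed.
* 2D projection only: no z-dimension, no 3D rotation axis inference; the
  planar rotation represents the image-plane projection of one rotational
  degree of freedom.
* The sweep's smallest-diameter/slowest-D corner is sensitive to the
  rotation geometry scheme; conclusions there are qualitative
  (bias exists and is large), not quantitative.
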