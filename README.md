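# tetherSMT

Simulation and bias analysis for single-molecule tracking (SMT) inside
biomolecular condensates.

## The problem

In vitro, biomolecular condensates behave as colloidal droplets: on a
passivated but untethered surface the whole condensate translates and
rotates by thermal motion. Trajectories of guest molecules tracked inside
such a droplet mix intra-condensate diffusion with whole-condensate
motion, which can systematically over- or underestimate apparent diffusion
coefficients, anomalous exponents and step sizes — most severely for
slowly diffusing, confined molecules (structured mRNAs) in small
condensates, and not at all for fast unstructured RNAs whose diffusion
outruns the condensate motion. tetherSMT is aimed at experimentalists who
need to decide whether surface tethering is required for their system, and
at analysts who want a ground-truth-known test bed for SMT pipelines.

## What it computes

**Simulation.** Guest molecules move by 2D fractional Brownian motion with
`MSD(tau) = 4 D tau^alpha` (Hurst exponent `H = alpha/2`); whole-condensate
Brownian rotation is added per step as one shared random angle about the
condensate centre, with rate from the Stokes–Einstein relation for a
sphere, `omega = kB T / (4 pi eta r^3)`. Tethered condensates are the same
simulation with rotation disabled, sharing molecular noise exactly.

**Analysis.** Time-averaged MSD per track; log–log fit
`log MSD = alpha log tau + log(2 n D)` for the apparent exponent;
motion-blur-corrected fit `MSD = 2 n D tau + 2 sigma^2 - 4 D R tau`
(`n = 2`, `R = 1/6`) for `D_app` and localization error; step-size and
fluctuation summaries; the track filters used before ensemble analysis;
rotation-referenced kinematics (angle series, angular velocity and
acceleration, velocity autocorrelation, phase-space area); Mann–Whitney /
Kruskal–Wallis tests with Cliff's delta effect sizes; mask circularity
`4 pi A / P^2`; and paired tethered/untethered Sobol sweeps rendered as
bias heatmaps (untethered/tethered ratio of apparent metrics) with a
tethering-necessity guideline check.

## Worked example

A slow, confined molecule (`D = 0.004` um^2/s, `alpha = 0.5`) in a small
(0.8 um) condensate, 1600 tracks per condition pooled over 4 condensates,
tethered vs untethered with paired molecular noise:

```r
library(tetherSMT)
mk <- function(rotation) sim_params(D = 0.004, alpha = 0.5, diameter = 0.8,
                                    dt = 0.05, n_steps = 20,
                                    n_molecules = 400,
                                    rotation_enabled = rotation, seed = 7)
teth   <- analyze_tracks(simulate_condensates(mk(FALSE), 4))
unteth <- analyze_tracks(simulate_condensates(mk(TRUE), 4))
bias_ratio(teth, unteth)
compare_groups(teth$mean_step_nm, unteth$mean_step_nm,
               names = c("tethered", "untethered"))
```

prints (seed 7):

```
median D_app tethered:   0.0040 um^2/s
median D_app untethered: 0.0059 um^2/s
bias ratio D_app: 1.33   bias ratio alpha: 1.08
  statistic      p_value cliffs_delta effect_label annotation
1     63806 7.228175e-07    -0.202425        small       ****
```

Read: the tethered pipeline recovers the ground-truth `D` exactly at the
median, while the lack of tethering inflates `D_app` by 1.33x and the
apparent exponent by 8% for this condition; the untethered step-size
distribution is significantly larger (negative delta: tethered steps are
smaller). A 0.8 um condensate rotates at
`rotational_diffusivity(0.4) = 1.023` rad^2/s under the default
temperature and viscosity. For the full parameter-space picture use
`run_sweep()` + `build_heatmap()` + `guideline_check()`; the practical
outcome is a frontier: tethering matters only below it (slow molecules in
small condensates), and condensates larger than ~2 um need no tethering
for any physiological `D`.

## Command line

```sh
exec/tethersmt simulate --seed 1 --D 0.01 --alpha 0.5 --diameter 0.8 \
    --out sim.csv
exec/tethersmt analyze --in sim.csv --dt 0.05 --out metrics.csv
exec/tethersmt compare --a metrics_teth.csv --b metrics_unteth.csv
exec/tethersmt sweep --n-points 32 --n-molecules 200 --seed 1 --out sweep.csv
exec/tethersmt heatmap --in sweep.csv --alpha 0.5 --out heatmap.csv
exec/tethersmt fixtures --regime mRNA_200ms --seed 1 --out-dir fixtures/
```

Every run writes a provenance JSON (config hash, seed, version, filter
audit) next to its outputs. File schemas are documented in
`inst/formats.md`; a small synthetic example spot table and mask live in
`inst/extdata/`.

## Documentation

The methods vignette (`vignettes/tethering-bias.Rmd`) describes the model
and its conventions — in particular the per-step rotation-angle
distribution and the small-angle vs exact rotation geometry, both of which
materially change the bias landscape — plus filter thresholds, statistics
conventions, and what the synthetic fixtures do and do not emulate.
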