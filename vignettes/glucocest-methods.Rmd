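---
title: "Models and methods behind glucocest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glucocest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`glucocest` implements a complete in-silico counterpart of a glucose-weighted
CEST (glucoCEST) MRI study in a rodent model of Alzheimer's disease: the
physics of the phantom optimisation experiments, the Z-spectrum processing
chain, dynamic glucoCEST-enhancement (GCE) mapping during a glucose infusion,
diffusion-tensor ADC/FA maps, and the small-sample statistics applied to the
resulting cohort tables. This vignette documents the models, the defaults,
and the design decisions, in that order of importance.

## The forward model

### Bloch--McConnell equations

Saturation transfer is simulated with the coupled Bloch--McConnell equations
for one water pool and any number of dilute solute pools. For pool $i$ with
equilibrium magnetisation $M_0^i$ (water normalised to 1, solutes to their
proton fraction $f_i = c_i / c_w$ with $c_w = 111$ M), relaxation rates
$R_{1,2}^i = 1/T_{1,2}^i$, chemical-shift offset $\Delta\omega_i$ relative to
the saturation frequency and continuous-wave amplitude
$\omega_1 = 2\pi\,\gamma B_1$ ($\gamma = 42.577$ Hz/µT), the evolution is the
linear affine system

$$\dot M = A M + c,$$

where $A$ couples $(M_x, M_y, M_z)$ within each pool through precession,
saturation and relaxation, and couples solute pools to water through
first-order exchange with rates $k_i$ (solute to water) and $k_i f_i$ (water
to solute, detailed balance). Propagation over an interval uses the matrix
exponential of the augmented $(3n{+}1)$ system, which is exact for the linear
model and unconditionally stable, so fast-exchanging pools need no step-size
control. A generic stiff ODE integration and the algebraic fixed point
$M_\infty = -A^{-1}c$ serve as independent cross-checks in the test suite,
not as the implementation.

### The acquisition cycle

Z-spectrum amplitudes depend on the repetition history, not only on the
saturation block. Each repetition is modelled as

1. readout with complete spoiling (all magnetisation set to zero),
2. free recovery for $TR - t_{sat}$,
3. CW saturation for $t_{sat}$ at the current offset,
4. readout of the water longitudinal magnetisation.

The cycle is iterated to its periodic steady state (fixed-point tolerance
$10^{-8}$; with full spoiling the cycle map is memoryless and converges
immediately, but the iteration is kept explicit). This is what gives the
repetition-time sweep its meaning: longer $TR$ allows more longitudinal
recovery before saturation and raises the apparent asymmetry. The reference
signal $S_0$ is simulated with the *same* cycle saturated at the reference
offset (10 kHz), matching acquisitions whose "unsaturated" image is in fact
irradiated far off resonance.

Two consequences of the spoiled cycle are worth knowing. First, when the
recovery interval is short the saturation block starts from almost zero
magnetisation, and on-resonance nutation can transiently drive water $M_z$
a few parts in $10^3$ *below* zero before relaxation damps it; simulated
$z$-values are therefore validated against $[-10^{-2},\,1]$ rather than a
hard zero floor. Second, saturation-time sweeps keep the recovery dead time
of the template scheme ($TR = t_{sat} + 0.04$ s by default) so that
$t_{sat} \le TR$ always holds and the 5-s point of the sweep coincides with
the base protocol.

### Frozen parameter set

The phantom papers this package emulates report concentrations, pH, B1,
timings and offsets, but not exchange rates or relaxation times. Those live
in a single editable preset table
(`system.file("extdata", "pool_presets.csv", package = "glucocest")`),
fixed once for the whole package:

| quantity | default | rationale |
|---|---|---|
| water T1/T2, phantom | 3.0 s / 1.0 s | PBS + 1% agarose at room temperature |
| water T1/T2, in vivo | 2.0 s / 0.06 s | rat brain at 7 T |
| glucose pool | +1.2 ppm, 5 H/molecule | single effective hydroxyl pool; the analysis reads a single 0.9-ppm asymmetry value, so a 3-site model adds nothing downstream |
| glucose $k_{exch}$ (pH 7.4) | 2500 s$^{-1}$ | literature range for hydroxyl exchange near neutral pH, fixed so the forward model sits in the regime of the published phantom series (about 10% effect at 25 mM under the base protocol, rising to about 24% at 100 mM) |
| glucose T1/T2 | 1.0 s / 0.01 s | generic dilute-solute values |
| Cr/Glu/GABA/Cho pools | presets in the CSV | qualitative metabolite selectivity only |
| ppm-to-Hz | 298.06 Hz/ppm | 7 T; 0.9 ppm = 268.3 Hz |

pH enters through base-catalysed hydroxyl exchange,
$k(\mathrm{pH}) = k_{ref}\,10^{\mathrm{pH}-\mathrm{pH}_{ref}}$: one decade
per pH unit, matching the hydroxide-driven mechanism. This reproduces the
observed negative pH dependence of the glucoCEST effect: far below the
intermediate-exchange optimum the effect grows with $k$, far above it the
saturation efficiency collapses.

The agarose semisolid (MT) pool is deliberately omitted: conventional MT is
symmetric to first order and the analysis is an asymmetry difference.

## Z-spectrum processing

Normalisation is the plain ratio $z = S_{sat}/S_0$; values above 1.05 are
flagged as corrupt. The asymmetry readout is

$$\mathrm{MTR}_{asym}(\Delta) = z(-\Delta) - z(+\Delta),$$

evaluated at $\pm 0.9\ \mathrm{ppm} \times 298.06\ \mathrm{Hz/ppm}$ by
natural cubic-spline interpolation — the 30-Hz acquisition grid does not
contain $\pm 268.3$ Hz, and nearest-sample evaluation was rejected as it
aliases the B0 correction. One shared spline implementation (common-knot
natural splines solved for many voxels simultaneously) backs the scalar and
the voxelwise paths, so a uniform image and the scalar pipeline agree to
machine precision by construction.

B0 correction follows the spectrum-minimum convention: the water centre is
the argmin of a smoothing spline fitted within ±300 Hz of nominal zero
(generalised cross-validation selects the smoothing, so noise-free spectra
are interpolated nearly exactly; at least 7 points are required and a
minimum on the window boundary is an explicit failure). The measured
spectrum is then resampled at `offsets + shift`; grid points whose source
falls outside the measured support are marked invalid and excluded — masked
voxels always carry an explicit validity flag, never silent zeros. An
acquired B0 map can be supplied instead of the per-voxel estimate
(`b0 = "auto"`); the synthetic cohorts record their true field and the
pipeline consumes it directly.

## Dynamic GCE analysis

Per timepoint, the glucoCEST image is the voxelwise
$\mathrm{MTR}_{asym}(0.9\ \mathrm{ppm})$ map. The enhancement map is the
infusion-state mean minus baseline,

$$\mathrm{GCE} = \tfrac12\left[m(\mathrm{inf40}) + m(\mathrm{post10})\right] - m(\mathrm{baseline}),$$

so glucose uptake yields positive GCE and reduced uptake reduces it; the
opposite subtraction order is available via `sign = "pre-post"` since the
verbal description of the difference is ambiguous in the source protocols.
ROI time courses report both the raw ROI-mean $\mathrm{MTR}_{asym}(t)$ and
its baseline-subtracted change, because published time-course figures do not
always state which of the two they plot. Bilateral structures are analysed
as left/right unions by default with the individual sides also reported, and
all ROI means are taken over the voxels valid at *every* timepoint, which
makes the ROI mean of the GCE map and the time-course arithmetic exactly
consistent.

## Diffusion maps

With $S_0$ plus exactly six gradient directions the log-linear tensor system
$\ln(S_i/S_0) = -b\, g_i^T D g_i$ is square, so the noiseless fit is an
exact inversion (tested to $10^{-10}$ relative). ADC is the eigenvalue mean
(trace/3); FA is $\sqrt{3/2}\,\lVert\lambda - \bar\lambda\rVert /
\lVert\lambda\rVert$ with negative eigenvalues clamped to zero first, which
keeps FA in $[0, 1]$ under noise. Voxels with non-positive signals or
$S_i \ge S_0$ are masked out rather than fitted — with six equations and six
unknowns there is nothing to downweight. Weighted least squares is
deliberately not offered; the emulated analysis computes plain maps.

## The synthetic cohort generator

The generator reproduces the *statistical design* of the emulated in vivo
study: two groups of six animals, a seven-timepoint infusion protocol
(baseline; 10/20/30/40 min during infusion; 10/20 min post), per-animal
dynamic CEST series, paired six-direction DWI, and a per-animal hippocampal
myo-inositol value linearly linked to the animal's true GCE.

Study-condition defaults, fixed once in `cohort_spec()`:

* group uptake curves (baseline-anchored ΔMTRasym at the seven timepoints):
  controls rise to a plateau of **0.03** during the infusion and hold it;
  AD animals reach a lower plateau of **0.012** early and then decline
  below baseline, with the curve minimum at the 40-min timepoint — the
  shape reported for amyloid-injected rats (lower uptake; lowest signal at
  40 min with no post-infusion recovery to control levels);
* animal-level random effects of sd **0.005** on both the baseline
  MTRasym and the plateau (the plateau effect scales the whole curve), so
  group tests face realistic between-animal variance;
* baseline MTRasym(0.9 ppm) of **0.035** in both groups; the elevated AD
  baseline seen in vivo can be emulated by raising the AD entry, but it is
  off by default so that recovery tests are clean;
* Gaussian image noise of sd **0.01** on the normalised signal (SNR ≈ 100,
  where the Rician floor is negligible); a smooth bilinear B0 field within
  roughly ±50 Hz;
* a 32 × 32 grid with parametric elliptical ROIs (whole brain, bilateral
  hippocampus, bilateral parietal cortex). Half the acquisition matrix of
  the emulated protocol is used because the phantom geometry is uniform
  within ROIs, so finer sampling only rescales voxel counts; it is a
  generator default, not a constraint of the analysis code, which accepts
  any grid;
* the metabolite link $mI = \alpha + \beta\,\mathrm{GCE} + \varepsilon$
  with $\alpha = 4$ mM, $\beta = 50$ mM per unit GCE and $\varepsilon$
  chosen so the *population* $R^2$ of the link is 0.626, the strength of
  the published GCE--mI association.

Per-voxel spectra are produced by the same Bloch--McConnell forward model:
a calibration curve MTRasym(concentration) is simulated once per
scheme/parameter set (memoised), inverted monotonically, and the spectrum at
the required target is interpolated across the concentration grid — accurate
to about $10^{-6}$ in the recovered asymmetry, as the round-trip tests
verify. The effective glucose concentration here is a modelling device that
absorbs every CEST-active contribution to the baseline signal, which is why
it can exceed physiological glucose levels. B0 is applied by resampling each
spectrum at the shifted offsets; all ground truth (random effects, curves,
true GCE, field coefficients) is recorded in a manifest for round-trip
testing, and a fixed seed regenerates a byte-identical cohort.

What the generator does **not** emulate: anatomy (no atlas geometry),
glucose pharmacokinetics (curves are specified, not derived from an input
function), Rician noise statistics at low SNR, B1 inhomogeneity, motion, and
partial-volume effects. Passing recovery tests therefore demonstrate the
correctness of the processing chain under the stated image model, not
robustness to those confounds.

## Statistics

The group-comparison flow mirrors small-sample preclinical practice:
optional outlier screening, normality and variance gates, then the test.
Screening uses the 1.5 × IQR rule as the reproducible surrogate for
graphical stem-and-leaf inspection; flagged values are only removed when
explicitly requested, and removals are logged in the result. Shapiro--Wilk
per group and Levene's test (centre = mean) gate at $\alpha$: if all pass,
the two-sided pooled-variance t-test; otherwise the Mann--Whitney U test
with normal approximation and tie correction (the emulated analysis does
not name its nonparametric test; Mann--Whitney is the standard choice).
Two-sided testing is assumed throughout, all intermediate p-values are
reported, and two identical constant samples return an explicit "no test"
result rather than an error or a fabricated p-value. No multiple-testing
correction is applied, matching the emulated analysis.

The GCE--metabolite association is ordinary least squares with
$R^2 = 1 - SS_{res}/SS_{tot}$ and the two-sided slope p-value. A
square-root transform helper is provided for latency-type data, though the
behavioural analysis it served is out of this package's scope.

## Numerical choices and degenerate inputs

* Matrix exponentials via `Matrix::expm` (scaling-and-squaring Padé);
  non-finite propagators and $z$ outside $[-10^{-2}, 1]$ raise errors
  ("stiff/ill-conditioned") instead of returning garbage, and exchange
  rates with $k\,t_{sat} > 10^9$ are rejected up front.
* All interpolation is natural cubic spline; the shared implementation is
  validated against `stats::spline(method = "natural")` to $10^{-10}$.
* Voxels are grouped by their B0 edge-trim pattern so the per-voxel spline
  systems factor into a handful of multi-column solves; this is a pure
  performance device with bitwise-identical arithmetic to the scalar path.
* The B0 search window is ±300 Hz; an estimate on the window edge, too few
  points, or a shift beyond half the spectrum support are errors.
* Degenerate statistics inputs (constant groups, constant regressor,
  fewer than 3 observations) produce explicit errors or "no test" results.

## Test problem sizes

The suite exercises the physics on coarsened offset grids (30--300 Hz
steps, identical physics), the cohort pipeline on 16 × 16 and 32 × 32
grids, 100-seed bias checks, 200-replicate power checks for the group
effect and the AD time-course minimum, and 500-replicate coverage checks
for the regression stage. These sizes were chosen so the whole suite runs
in minutes while keeping every Monte-Carlo margin wide relative to its
sampling error.

## Known limitations

Pulsed saturation trains, relayed-NOE and semisolid MT pools, temperature
dependence, B1 mapping/correction and vendor raw formats are out of scope.
The exchange-rate and relaxation presets are literature defaults for one
field strength and temperature regime; quantitative use at other conditions
requires editing the preset table. The spectrum-minimum B0 estimator
inherits a small bias (well under 1 Hz) from asymmetric CEST lobes adjacent
to the water dip; the acquired-map pathway avoids it.
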