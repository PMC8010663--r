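# glucocest

Simulation and analysis of glucose-weighted chemical exchange saturation
transfer (glucoCEST) MRI, built for preclinical studies of brain glucose
uptake — in particular the design where dynamic glucoCEST imaging during a
D-glucose infusion is compared between an Alzheimer's-model rodent group and
controls, alongside DTI maps and MRS metabolite values.

The package covers the whole chain:

* **Forward physics** — a multi-pool Bloch–McConnell simulator under
  continuous-wave saturation, embedded in a cyclic
  readout–recovery–saturation model of the acquisition, for phantom
  optimisation experiments (metabolite selectivity, glucose concentration
  and pH series, B1 / t_sat / TR sweeps).
* **Z-spectrum processing** — normalisation `z = Ssat/S0`, spectrum-minimum
  or map-based B0 correction, and the asymmetry readout
  `MTRasym(0.9 ppm) = [Ssat(−0.9 ppm) − Ssat(+0.9 ppm)]/S0`, evaluated by
  cubic-spline interpolation, for single spectra and per-voxel image stacks.
* **Dynamic GCE** — per-timepoint glucoCEST maps over a 7-point infusion
  protocol and the enhancement map
  `GCE = mean(map(40 min), map(post 10 min)) − map(baseline)`, plus ROI
  time courses and tidy cohort tables.
* **DTI** — exact tensor inversion from S0 + six directions, ADC (mean
  diffusivity) and FA maps, FSL-style bvec/bval IO.
* **Synthetic cohorts** — a seeded generator that emulates the study design
  (n = 6 + 6, group-specific uptake curves, animal-level variance, B0
  fields, noise, paired DWI, a GCE-linked myo-inositol table) so every
  stage is testable without scanner data.
* **Statistics** — 1.5×IQR outlier screening, the Shapiro–Wilk + Levene
  gated choice between the pooled t-test and the Mann–Whitney U test, and
  OLS regression for the GCE–metabolite association.

See `vignettes/glucocest-methods.Rmd` for the models, defaults and design
decisions.

## Worked example

Simulate the 25 mM D-glucose phantom (pH 7.4, B1 = 1.5 µT, t_sat = 5 s,
TR = 5.04 s, offsets ±1500 Hz in 30 Hz steps) and read off the glucoCEST
effect:

```r
library(glucocest)

sys <- glucose_phantom_system(25, ph = 7.4)
z   <- simulate_zspectrum(sys, phantom_scheme())
mtr_asym(z, 0.9)
#> [1] 0.09912115

cest_sweep(sys, phantom_scheme(), "concentration", c(25, 50, 75, 100))
#>   value mtr_asym peak_ppm peak_asym
#> 1    25   0.0991   0.6875    0.1068
#> 2    50   0.1642   0.8110    0.1664
#> 3    75   0.2065   0.9044    0.2065
#> 4   100   0.2336   0.9796    0.2360
```

The 25 mM tube shows a ~9.9% asymmetry at 0.9 ppm; across 25–100 mM the
effect grows to ~24% and the asymmetry-curve peak moves from 0.69 to
0.98 ppm — the concentration dependence and upfield peak shift that phantom
optimisation experiments report.

A full synthetic cohort, through the dynamic pipeline and the statistics
stage:

```r
co  <- generate_cohort(cohort_spec(seed = 1))
tab <- cohort_table(lapply(co$animals, `[[`, "series"), co$groups,
                    rois = "total_brain")
tapply(tab$gce, tab$group, mean)
#>      ad control
#> -0.0071  0.0290

compare_groups(tab$gce[tab$group == "control"], tab$gce[tab$group == "ad"])
#> <group_comparison> t_test stat=14.56 p=4.652e-08
#>   gates: shapiro a=0.438 b=0.5, levene=0.0875 (alpha=0.05)

mi <- cohort_metabolite_table(co)
regress(tab$gce[match(mi$animal, tab$animal)], mi$mi)
#> <gce_regression> y = 3.692 + 51.21 x, R^2 = 0.798, p = 9.006e-05, n = 12
```

Control animals recover their configured uptake plateau (ΔMTRasym ≈ 0.03),
the AD group's enhancement is significantly lower (here negative, because
the AD uptake curve declines below baseline late in the infusion), the
gated decision flow lands on the t-test, and the per-animal myo-inositol
values correlate positively with GCE.

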