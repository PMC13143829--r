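# collmot

Quantitative tools for the mechanobiology of epithelial collectives:

* **Collective motility by PIV** — windowed cross-correlation particle image
  velocimetry on time-lapse monolayer movies, yielding the total and
  drift-corrected r.m.s. velocities, the radial velocity–velocity
  correlation function with an exponential fit for the correlation length
  ξ, and the flocking alignment index. These are the order parameters used
  to place a tissue relative to the jamming transition and to detect
  flocking (solid-like, collectively drifting) states.
* **Spheroid wetting** — normalized spreading area A(t)/A(0) and the
  average wetting speed (µm/h) of 3-D spheroids spreading on ECM-coated
  substrates, from binary mask series.
* **TMA scoring and survival** — per-patient ECM scores (0–5: one point per
  stromal marker — fibronectin, collagen I, SMA, laminin, vinculin — above
  the cohort median), YAP-high/low groups, the <100-cell patient exclusion
  rule, and hand-implemented Kaplan–Meier / log-rank survival comparison.
* **Synthetic data with ground truth** — seeded generators for speckle
  movies advected by flows of known drift and correlation length,
  expanding-disk mask series of known front speed, and cohort tables with
  known ECM/YAP groups and hazard ratio, so every estimator above is
  validated end to end.

## The statistics at the core

For a velocity field `v_t(x)` on the grid of interrogation-window centres:

```
v_RMS^tot(t)  = sqrt( <|v_t(x)|^2>_x )
v_t^d.c.(x)   = v_t(x) - <v_t(x)>_x
C_vv(dx, t)   = <v^d.c.(x+dx) . v^d.c.(x)>_x / <|v^d.c.(x)|^2>_x
C_vv = exp(-dx / xi)          (least-squares fit -> correlation length)
a_t(x)        = cos angle( <v_t(x)>_x , v_t(x) )   (alignment index)
```

The ECM score counts, per patient, the stromal markers whose patient-level
median intensity lies strictly above the cohort median (0–2 = ECM-low,
3–5 = ECM-high); survival between groups is compared with the product-limit
estimator and a two-group log-rank test.

## Worked example

The `analysis/` scripts run the whole workflow on synthetic data
(`01_synthetic_data.R` → `04_tma_survival.R`). For instance, PIV on a
flocking-like movie (uniform drift) versus a jamming-like movie (correlated
flow with decaying amplitude):

```sh
$ Rscript analysis/01_synthetic_data.R
$ Rscript analysis/02_monolayer_motility.R
flocking: v_RMS^tot 6.2 um/h, v_RMS^d.c. 0.4 um/h, mean alignment 0.999
jamming: v_RMS^tot falls 2.2 -> 0.5 um/h over 6 chunks
```

The flocking monolayer moves fast and coherently — nearly all of its
r.m.s. velocity is shared drift (alignment ≈ 1) — while the jamming
monolayer's velocity decays toward arrest. Wetting and cohort scoring:

```sh
$ Rscript analysis/03_spheroid_wetting.R
imposed 10 um/h -> measured 10.00 um/h (A48/A0 = 33.7)
$ Rscript analysis/04_tma_survival.R
excluded 5 patients below the 100-cell rule; 193 scored
log-rank ECM-high vs ECM-low: chi-square 19.91, p = 8.1e-06
```

The synthetic cohort builds in a hazard ratio of 2 for ECM-high patients;
the scoring pipeline recovers every patient's constructed ECM score and the
log-rank test detects the survival split, while YAP groups (no built-in
effect) stay null.

## Layout

```
R/                  package code (PIV, metrics, wetting, TMA, generators)
analysis/           numbered workflow drivers writing tables to results/
scripts/acceptance.R  headline-number reproduction
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (models, parameters, design choices)
```
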