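---
title: "Quantifying collective motility, wetting and ECM scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collective motility, wetting and ECM scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collmot)
```

# Overview

`collmot` quantifies how confluent epithelial monolayers move collectively,
how 3-D spheroids spread ("wet") on matrix-coated substrates, and how
stromal matrix phenotypes scored on multiplexed tissue microarrays (TMAs)
stratify patient survival. Every stage consumes either real data in standard
formats (multi-frame TIFF movies, binary mask series, per-cell CSV tables)
or the package's own seeded synthetic generators, which carry known ground
truth so each estimator can be validated end to end.

This vignette records the models, the parameter choices and their
rationale, the numerical decisions, and what validation on synthetic data
does and does not demonstrate.

# Particle image velocimetry

## Model

A movie is divided into square interrogation windows; for the window at
position $x$ the displacement $\Delta r$ between the frames at $t$ and
$t+\Delta t$ is the location of the peak of the intensity cross-correlation,
giving a local velocity $v_t(x) = \Delta r / \Delta t$. Defaults follow
standard practice for epithelial monolayers imaged at ×20 with ~50 px cells:
80×80 px windows (slightly larger than one cell), 50% window overlap, a
1-frame lag, and temporal averaging of the per-pair fields over 20-frame
chunks (200 min at a 10-min frame interval) advancing with 50% overlap.

## Numerical choices

* **Correlation estimator.** We compute the zero-normalized cross-correlation
  (ZNCC) over all integer lags with zero-padded FFTs: at every lag the
  correlation coefficient of the *overlapping* parts of the two windows,
  each locally mean-subtracted and variance-normalized. Unlike plain
  circular correlation (biased by wraparound) or Hann-tapered correlation
  (biased toward small displacements by the taper), the ZNCC carries no
  bias from the finite window support; on noise-free synthetic drifts the
  residual error is a few hundredths of a pixel. Lags with less than 25%
  window overlap are excluded, which also enforces the $|\Delta r| \le$
  window/2 search bound.
* **Subpixel refinement.** Three-point Gaussian interpolation per axis at
  the integer peak (the standard PIV estimator), falling back to parabolic
  interpolation when a neighbour is non-positive.
* **Validation.** A constant (zero-variance) window is flagged invalid
  rather than raising. Vectors failing a normalized-median test against
  their 8 neighbours (threshold 2, noise floor 0.1 px) are replaced by the
  local median.
* **Chunk averaging.** A chunk node is reported only when at least half the
  chunk's fields are valid there; its vector is the mean of the valid ones.
* **Coordinates.** 0-based pixel indices, origin top-left, y downward;
  vectors stored as $(v_x, v_y)$ in px/frame, with µm/h obtained exactly as
  px/frame × pixel size × 60 / frame interval. Partial windows at the far
  image edge are discarded, not padded.

# Motility statistics

For each chunk-averaged field $v_t(x)$:

* total r.m.s. velocity $v_\mathrm{RMS}^\mathrm{tot}(t) =
  \sqrt{\langle |v_t(x)|^2\rangle_x}$;
* drift-corrected velocity $v^{d.c.}_t(x) = v_t(x) -
  \langle v_t(x)\rangle_x$ and its r.m.s. — the two satisfy
  $(v^\mathrm{tot}_\mathrm{RMS})^2 = (v^{d.c.}_\mathrm{RMS})^2 +
  |\langle v\rangle|^2$ exactly, which the tests assert to $10^{-9}$;
* the radial velocity–velocity correlation
  $C_{vv}(\delta x, t) = \langle v^{d.c.}_t(x+\delta x)\cdot
  v^{d.c.}_t(x)\rangle_x / \langle |v^{d.c.}_t(x)|^2\rangle_x$,
  accumulated over all node pairs in radial bins (default width: one grid
  spacing); the self-pair bin is 1 by construction;
* the correlation length $\xi$ from a least-squares fit of
  $C_{vv}(\delta x) = e^{-\delta x/\xi}$ — the decaying exponential; a
  growing exponential cannot describe a correlation that starts at 1 and
  decays. The fit runs from the first off-origin bin to the first bin with
  $C_{vv} \le 0.05$, directly on the curve (not log-transformed, so
  near-zero bins need not be discarded). A curve that stays near 1
  (the flocking limit) pegs the fit at its upper bound and is flagged, with
  $\xi$ reported as at least the field size;
* the alignment index $a_t(x)$: the cosine between the field's mean
  velocity and each local vector; near 1 everywhere indicates flocking.

The jamming phase plane plots $\xi(t)$ against
$v^{d.c.}_\mathrm{RMS}(t)$; `phase_trajectory()` emits that time-ordered
pair sequence.

## Resolution of the correlation length, and the windowed inversion

The velocity PIV reports is the flow averaged over each interrogation
window. For flows whose correlation length $\xi$ is not much larger than
the window, this averaging inflates short-range correlation (two windows
offset by half their size share half their support) while the zero-mean
constraint of a finite field depresses the tail; the plain exponential fit
then measures the *smoothed* field, not the flow. This is a physical
resolution limit, not an implementation artifact: on synthetic flows the
measured field matches the window-averaged truth at $r > 0.9$, and their
correlation curves coincide.

When the quantity of interest is the true flow scale and the measurement
configuration is known — benchmarking, simulation studies — the package
therefore provides `fit_flow_xi()`: the measured curve is fitted against
its exact expectation for an exponential-spectrum flow
($P(k)\propto(1+(k\xi)^2)^{-3/2}$, the 2-D spectrum of $e^{-r/\xi}$)
synthesized on the periodic domain with the $k=0$ mode removed and observed
through the window's squared transfer function. Bins are evaluated at their
mean pair separation and weighted by pair count. The box transfer function
alone describes the measurement — the window truncates the intensity
features it correlates, so no extra feature-footprint smoothing is applied.
Ground-truth recovery studies use a 48 px window (resolution-matched to the
20–80 px scales probed) rather than the 80 px monolayer default, on domains
of 400 px ($\xi$ = 20, 40) and 640 px ($\xi$ = 80): a fixed window cannot
resolve scales far below its own size, and the domain must hold many
correlation lengths for a single realization to constrain $\xi$. With this
design the median recovered $\xi$ over seeds tracks the truth at all three
scales (the acceptance suite asserts agreement within 25%); single
realizations still scatter by tens of percent, which is inherent to
estimating a correlation length from one finite field realization.

# Synthetic movies

The generator renders band-limited speckle (Gaussian-filtered white noise,
feature size ≈ 50 px to match a typical cell) and advects it with an
imposed flow: uniform drift (exact Fourier shifting, accumulated from the
pristine texture so interpolation error never compounds), spatially
correlated flow of known $\xi$ (periodic bilinear warping), a rigid vortex,
or any of these with a temporal half-life for jamming-like slow-downs. True
per-pair velocity fields are stored with the movie. Correlated fields are
spectrally synthesized, recentred to exactly zero mean, and rescaled to the
requested r.m.s. exactly.

What this emulates — and what it does not: the flows are imposed, not
emergent (no cell mechanics, no rearrangements); intensities are clean
speckle, not phase-contrast cells with lamellipodia, mitoses and debris.
Passing the synthetic benchmarks demonstrates the estimators are unbiased
and correctly calibrated on known flows at realistic texture scales; it
does not by itself guarantee accuracy on low-contrast or artifact-laden
microscopy.

# Spheroid wetting

Masks are reduced to areas (pixel count × pixel area), normalized to the
area at time 0, and to an equivalent-circle radius
$r(t) = \sqrt{A(t)/\pi}$. The average wetting speed is the least-squares
slope of $r(t)$ in µm/h: an area-based definition (matching the measured
quantity) robust to irregular fronts, with an endpoint
$(r(T)-r(0))/T$ alternative behind a flag. The reported speed scales
exactly linearly with the pixel size, and nested mask series always give a
non-negative speed. Segmentation of raw wetting movies is out of scope; the
module consumes masks.

# TMA scoring and survival

The scoring pipeline mirrors standard multiplexed-TMA practice:

1. **Exclusion.** Patients with fewer than 100 quantified cells in the
   stromal *or* epithelial compartment are removed (boundary inclusive:
   exactly 100 is retained).
2. **Aggregation.** Per patient, pooling all cores: the median stromal
   *extranuclear* intensity of each of fibronectin, collagen I, SMA,
   laminin and vinculin, and the mean *nuclear* YAP over tumour-epithelial
   cells. Junctional (extranuclear, epithelial) β-catenin is aggregated
   when present, with no survival claim attached.
3. **ECM score.** For each marker the across-patient median (computed on
   the filtered cohort — the filter runs first) is the threshold; a patient
   scores one point per marker *strictly above* it, giving 0–5. Ties at the
   median score no point: with continuous intensities ties have measure
   zero, and the literal reading is the defensible one. Scores 0–2 are
   ECM-low, 3–5 ECM-high. YAP-high/low is the same rule with one marker.
4. **Survival.** A hand-implemented Kaplan–Meier product-limit estimator
   (ties processed events-before-censorings) and two-group log-rank test
   with the hypergeometric tie-corrected variance and no continuity
   correction. Both are cross-checked in the tests against the `survival`
   package, which serves as an independent oracle only.

The synthetic cohort draws per-cell intensities lognormally around two
well-separated levels; per marker, exactly half of the *filter-passing*
patients are high (rank-based on correlated latent propensities, so scores
spread over 0–5), which pins each dataset median into the gap between the
levels and makes the generator's truth exactly recoverable — the property
tests assert score recovery patient by patient. Survival times are
exponential with the ECM-high hazard multiplied by a configurable ratio
(default 2, a moderate clinically plausible effect); censoring replaces the
event with a uniform draw before it at a configurable rate (default 0.3).
Cohort defaults are 198 patients with 5 forced below the cell-count
threshold, ~250 cells per compartment.

# Problem sizes and determinism

All randomness flows from one explicit seed per generator call (the RNG
state of the session is saved and restored), and the pipeline driver fans a
single seed out to fixed per-stage seeds, so identical configurations are
byte-identical. Validation problem sizes were chosen to make the test suite
informative yet quick: PIV accuracy on 240 px movies, correlation-length
recovery on 400–640 px movies over 5–11 seeds, log-rank operating
characteristics over 500 null and 100 alternative simulations of n = 200
cohorts.

# Known limitations

* Single-pass PIV only: no multi-pass window deformation, no optical flow;
  flows with strong in-window gradients are low-pass filtered as described
  above.
* `fit_flow_xi()` assumes the exponential-spectrum flow family and a known
  periodic domain; it is a benchmarking tool, not a general-purpose
  estimator for arbitrary tissue flows.
* Whether cell-free regions should be masked before PIV is data-dependent;
  no masking is applied by default.
* The per-chunk $\xi$ fit (rather than a fit to time-averaged curves) is
  the default; noisy chunks can fail the fit and are flagged rather than
  silently dropped.
* The wetting speed uses the full time window; a sub-interval fit is left
  to the caller via the mask series it supplies.
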