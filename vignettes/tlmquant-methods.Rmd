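---
title: "Quantifying gene expression heterogeneity from time-lapse microscopy"
author: "tlmquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene expression heterogeneity from time-lapse microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Isogenic microbial populations growing under uniform conditions often express
individual genes unevenly: expression can be noisy around a single level, or
outright bistable, with distinct ON and OFF subpopulations. Promoter–GFP
reporter fusions imaged by time-lapse fluorescence microscopy are the only way
to watch this heterogeneity develop in real time at single-cell resolution.
`tlmquant` implements the full analysis path from raw image pairs to corrected
heterogeneity numbers: for every time point it expects an 8-bit phase-contrast
image (cells dark on a bright field) and a registered 8-bit fluorescence image
of the same scene.

The pipeline has five stages, each exposed as ordinary R functions and chained
by `run_pipeline()`:

1. **Segmentation** of the phase image into a binary cell mask and particles.
2. **Quantification** of per-cell fluorescence through mask arithmetic.
3. **Normalization** against the image background.
4. **Population statistics and noise-baseline correction.**
5. **Visualization** as time-resolved intensity heatmaps and bar charts.

A ground-truthed synthetic image generator stands in for the microscope, so
every stage is testable against known truth.

## Segmentation

The segmentation follows the classic ImageJ operator sequence with clamped
(never wrapped) 8-bit arithmetic:

rolling-ball background subtraction → kernel convolution → automatic
threshold → binarization → 3×3 median despeckle → connected-component
particle analysis.

Choices that matter:

* **Background subtraction** estimates the smooth background as the grayscale
  morphological opening by a flat disc (default radius 50 px, the customary
  default for bacterial fields) and subtracts it. Phase-contrast images are
  *light-background* images, so the image is inverted first; the output
  carries cells bright on a levelled dark field. A small pre-closing
  (`smooth_radius`, default 3 px) is applied before the opening: phase
  contrast surrounds each cell with a bright halo rim, which after inversion is a
  narrow pit that a flat disc — unlike a physical rolling ball, which cannot
  descend into pits narrower than its curvature — would mistake for true
  background. Without the pre-closing the background estimate is depressed by
  tens of grey levels across the whole field and spurious particles appear
  everywhere; with it the residual background is ≤ 3 grey levels on the
  synthetic scenes. The exported `subtract_background()` defaults to the pure
  opening (`smooth_radius = 0`).
* **Convolution kernel**: a 5×5 centre-weighted sharpening kernel (centre 24,
  all other weights −1, weight sum zero, unnormalized). It responds strongly
  at intensity boundaries, which suits rods a few pixels wide; the kernel is
  a free parameter (`make_kernel()`) and should be adapted to cell geometry
  and exposure. A consequence worth knowing: on rods about as wide as the
  kernel, the rod *axis* produces a weak response and the binarized rod is
  hollow by one pixel; the despeckle stage (a majority filter on binary
  masks) refills it, which is one reason the stage order matters.
* **Threshold**: IsoData intermeans iteration — the returned integer `T`
  satisfies `T = round((mean(values ≤ T) + mean(values > T)) / 2)`. It is
  deterministic, and a constant image returns the constant itself so that
  downstream "above-threshold" binarization yields an empty mask. Otsu and
  fixed thresholds are available as configuration choices.
* **Particle analysis** labels 8-connected foreground components (4 available),
  filters by area (default minimum 20 px to suppress debris; no upper bound),
  and labels in row-major scan order. Border particles are kept by default
  (`exclude_edges` available). Touching cells form a single component and are
  *deliberately counted as one particle*: the pipeline performs no watershed
  splitting, and the tests pin this merge behaviour down with an
  attached-pair fixture.

## Quantification by mask arithmetic

Two measurement paths are implemented:

* **Faithful inverted-mask scheme**: compute `mask − fluor` clamped at 0, so
  background pixels vanish and a cell pixel of fluorescence *f* becomes
  255 − *f*; keep values ≥ 1 (thresholding away only the minimal grey value);
  per particle, recover `mean_raw = 255 − mean(inverted values)`. The scheme's
  edge case is reproduced on purpose: a saturated cell pixel (*f* = 255)
  inverts to 0 and silently drops out; a particle losing *all* its pixels
  this way is flagged invalid rather than reported as zero.
* **Direct region mean** (the default for new data): the plain mean of the
  fluorescence over the particle's pixels. On any particle without saturated
  pixels the two paths agree exactly, and the test suite enforces agreement
  to better than 1/255 across hundreds of randomized frames.

**Background** is estimated by the complementary trick: `fluor + mask`
clamped at 255 saturates every cell pixel, and the mean over pixels still
below 255 is the average background fluorescence — the whole image except the
cell areas (plus, as a faithful quirk, except background pixels that are
themselves saturated).

**Normalization** defaults to background subtraction,
`mean_normalized = mean_raw − mean_bg`, in arbitrary units (AU). Slightly
negative values for non-expressing cells are preserved, not clamped. A ratio
mode `(mean_raw − mean_bg) / mean_bg` is available behind a flag; subtraction
is the default because the downstream SD-versus-mean analysis operates on
intensity units.

## The noise baseline and corrected heterogeneity

The observed SD of cellular fluorescence within one image mixes biological
heterogeneity with measurement noise. For a homogeneously expressing control
(e.g. an IPTG-tunable promoter driving GFP at different induction levels),
that SD is essentially *all* noise, and it grows linearly with the image's
mean cellular fluorescence. `fit_noise_baseline()` therefore regresses SD on
mean by unweighted ordinary least squares with a free intercept (a
weight-by-n option exists but is off by default, matching a single pooled
regression over all control images). The result is a classed `noise_model`
with `print`, `coef`, `predict` and `summary` methods, serialized to JSON so
one control experiment can correct any number of test series.

`correct_heterogeneity()` then reports
`corrected = observed SD − (slope · mean + intercept)` per frame. Negative
corrected values are preserved: clamping would hide model misfit, and the
corrected trace of a homogeneous series should scatter around zero.

Per-frame statistics use the sample (n − 1) standard deviation, with SD 0 for
single-cell frames. Time-point summaries for bar charts pool the combined
mean and SD exactly as if the per-cell values had been concatenated
(reconstructed algebraically from per-frame n/mean/SD), selecting the nearest
frame to each requested time (earlier frame on ties) or pooling all frames
within an optional window.

Bar charts cannot distinguish highly noisy from bistable expression. As a
clearly labelled *extension* (not part of the classic pipeline, which offers
no bimodality statistic), `count_modes()` reports a descriptive per-frame
mode count: local maxima of a kernel density estimate, with shallow-valley
merging (a dip must fall below half the lower neighbouring peak) so sampling
ripple does not masquerade as bimodality. It is a descriptive aid, not a
formal test.

## Heatmaps

`build_heatmap()` histograms per-cell normalized intensities into fixed
global bins (default 64 over the observed range), one column per frame, and
the colour of each (time, intensity) bin encodes the *number of cells* in it
— this is what makes two coexisting subpopulations visible as two separated
bands. Values outside the configured range are counted into the edge bins so
column sums always equal per-frame cell counts. Colour schemes are CSV files
of (count upper bound, colour) rows; counts above the top bound saturate to
the last colour.

## The synthetic generator

`scenario_params()` + `generate_timeseries()` emulate the three study
scenarios:

* **homogeneous** — per-cell intensities from one normal distribution whose
  SD follows the measurement-noise calibration line SD = 0.1·mean + 2 AU,
  the line the noise-model recovery tests assume; four induction levels
  default to 20/50/100/180 AU, an 8-bit-headroom analogue of four inducer
  concentrations, and `simulate_control_series()` produces the corresponding
  (mean, SD) calibration points with 100 cells per image — enough sampling
  power that the regression recovers both coefficients within 10% from ~536
  image measurements.
* **noisy** — lognormal intensities with `sdlog = 0.5` (CV ≈ 53%). This value
  was chosen so the scenario taxonomy's intended ordering holds in
  expectation: at `sdlog = 0.6` the lognormal SD would *exceed* the bistable
  mixture's SD and the "noisy < bistable" ranking would be a coin flip.
* **bistable** — a two-component normal mixture, low mode 15 ± 5 AU, high
  mode 150 ± 15 AU, 30% high; daughters inherit the mother's mode.

Cells are rods rendered as capsules (rectangles with semicircular caps),
default width 5 px, newborn length 15 px, dividing at 30 px with 5% midpoint
jitter and one-hour doubling. Phase optics: background 180, cell interior 60,
a 2 px halo rim at 220, Gaussian read noise SD 2; fluorescence: background 8,
uniform cell interior at the true intensity (1 AU = 1 grey level), read noise
SD 2. Noise SD 2 grey levels is typical of 8-bit camera acquisitions. Every
frame comes with an exact per-pixel ground-truth label mask and a truth CSV.

Two layouts exist. The default **scattered** layout places an exponentially
growing number of *non-touching* cells independently per frame — the pipeline
does no tracking, so per-frame population statistics are unaffected, and
non-touching placement keeps per-cell truth unambiguous. The **colony**
layout runs the lineage simulation (growth, division, mode inheritance) and
renders the living population each frame; daughters are placed with a 2 px
gap, as cells on agarose push apart. Attached pairs for the documented
merge behaviour are generated on demand (`touching_pair()`).

What the generator does *not* emulate — and hence what passing tests do not
show about real data: phase-contrast optics (point-spread function, halo
physics beyond a uniform rim), uneven illumination, focus drift,
photobleaching, cell motility, and densely packed colonies where most
neighbours touch. Real images will need kernel and threshold adjustments and
will show merge-induced averaging that the scattered layout avoids.

## Numerical choices and degenerate inputs

* All 8-bit arithmetic clamps at 0 and 255; nothing wraps.
* Convolution replicates edges; morphology treats out-of-field pixels as
  neutral, which is equivalent to edge replication for min/max filters.
* A constant phase image segments to zero particles; a mask covering the
  whole image makes the background estimator fail loudly ("no background
  area"); an empty frame is skipped from statistics with a warning rather
  than reported as a zero row.
* The intermeans iteration is capped against cycling and returns the first
  revisited threshold, making it deterministic on adversarial histograms.
* `fit_noise_baseline()` refuses fewer than 3 points or a design with no
  spread in the means ("degenerate design").
* All randomness flows from explicit seeds; a pipeline rerun with the same
  configuration and seed reproduces CSV outputs byte for byte.

## Problem sizes used in validation

The shipped validation suite runs entirely on synthetic data: measurement
equivalence on 200 randomized 64×64 frames; segmentation recovery on five
fields of 20–200 non-touching rods (256²–512² px); noise-line recovery from
536 simulated control images; correction sanity on a held-out 15-point
homogeneous series; scenario separability end-to-end (images → segmentation →
quantification → correction) on five seeds of three matched scenarios at
224×224 px over five frames each. These sizes were chosen to exercise every
code path at meaningful statistical power while keeping a full validation run
in the minutes range on a single core.

## Known limitations

* No cell tracking or lineage reconstruction; all statistics are per frame.
* No watershed splitting: attached cells count as one particle, which biases
  per-cell means toward the average of the pair (documented, not corrected).
* The inverted-mask scheme drops saturated pixels by construction; use the
  direct scheme (default) when saturation matters.
* The noise baseline is linear; strongly nonlinear noise (e.g. at detector
  saturation) would need a different control model.
* One fluorescence channel is processed per invocation, though the data
  model carries several.
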