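# tlmquant

Visualization and quantification of gene expression heterogeneity in growing
microbial cells from time-lapse fluorescence microscopy.

Isogenic bacterial populations often express individual genes unevenly — from
mild noise around one level to full bistability, where ON and OFF
subpopulations coexist. This matters for differentiation (competence,
sporulation, motility in *Bacillus subtilis*) and for biotechnology, where
non-producing subpopulations cost yield. Time-lapse microscopy of
promoter–GFP reporter strains is the only way to watch this heterogeneity
develop in real time at single-cell resolution, and `tlmquant` is the
analysis side of that experiment: from registered 8-bit phase-contrast +
fluorescence image pairs to segmented cells, per-cell normalized intensities,
noise-corrected heterogeneity numbers, and time-resolved intensity heatmaps.

It is aimed at microbiologists running reporter-fusion time-lapse experiments
who want an open, scriptable, fully tested pipeline rather than a chain of
manual GUI steps.

## What it computes

For each time point *t* with phase image *P* and fluorescence image *F*
(both 8-bit, registered):

1. **Segmentation** — binary cell mask *M* from *P* via rolling-ball
   background subtraction (grayscale opening by a disc, light-background
   mode), sharpening convolution, IsoData intermeans threshold
   `T = round((μ_below + μ_above)/2)`, binarization, 3×3 median despeckle,
   and 8-connected particle analysis with an area filter. Touching cells are
   counted as one particle (no watershed).
2. **Quantification** — per particle, mean fluorescence via mask arithmetic:
   the faithful scheme measures `255 − mean((M − F)⁺)` over nonzero pixels;
   the default direct scheme takes the region mean of *F*. Background is the
   mean of `(F + M)` below 255 — the image minus the cell areas. Normalized
   intensity: `I = mean_raw − mean_bg` (AU).
3. **Heterogeneity** — per frame, mean and sample SD of *I* over cells. From
   a homogeneously expressing control (inducible promoter at several
   induction levels), the noise baseline `SD = a·mean + b` is fitted by OLS;
   corrected heterogeneity is `SD_obs − (a·mean_obs + b)`, which scatters
   around zero for homogeneous expression and stays positive for genuinely
   heterogeneous or bistable expression.
4. **Visualization** — per-frame intensity histograms stacked into a
   time × intensity heatmap (colour = cell count, so bistability shows as two
   separated bands) and grouped bar charts with pooled means ± SD.

A ground-truthed synthetic generator (`scenario_params()`,
`generate_timeseries()`) emulates homogeneous, noisy and bistable expression
in growing rod-shaped cells and replaces the microscope in all tests.

## Worked example

```r
library(tlmquant)

## simulate a bistable time series (2 h, 5 frames, 224x224 px)
params <- scenario_params("bistable", n_initial = 12, field = c(224, 224), seed = 7)
generate_timeseries(params, duration_h = 2, interval_h = 0.5, outdir = "demo")
series <- load_timeseries("demo")
print(series)
#> Time-lapse series: 5 frames, 224x224 px, t = 0..2 h, channels: gfp

## segment and quantify every frame
measurements <- do.call(rbind, lapply(series$frames, function(fr) {
  seg <- segment_frame(fr$phase)
  q <- quantify_frame(fr$fluor, seg$mask, seg$particles)
  cbind(data.frame(frame_index = fr$index, time_h = fr$time_h), q)
}))
head(measurements[, c("frame_index", "time_h", "particle_id", "area_px",
                      "mean_raw", "mean_bg", "mean_normalized")], 4)
#>   frame_index time_h particle_id area_px   mean_raw mean_bg mean_normalized
#> 1           0      0           1      86  13.872093 8.02377       5.8483234
#> 2           0      0           2     132 144.242424 8.02377     136.2186547
#> 3           0      0           3     142   8.950704 8.02377       0.9269346
#> 4           0      0           4     101 141.891089 8.02377     133.8673195
```

Particles 1 and 3 are OFF cells a few AU above background; particles 2 and 4
are ON cells around 135 AU — the two bistable modes, visible already in the
first frame.

```r
stats <- series_stats(measurements)

## noise baseline from a homogeneous four-level control, then correction
model <- fit_noise_baseline(simulate_control_series(seed = 7))
print(model)
#> Noise baseline: SD = slope * mean + intercept
#>   slope     0.099222 (SE 0.00059)
#>   intercept 2.0261 AU (SE 0.0627)
#>   r^2 = 0.9815 over 536 image measurements

corrected <- correct_heterogeneity(stats, model)
print(corrected[, c("time_h", "n_cells", "raw_sd", "predicted_sd", "corrected")], digits = 4)
#>   time_h n_cells raw_sd predicted_sd corrected
#> 1    0.0      12  65.26        7.038     58.22
#> 2    0.5      17  31.02        3.416     27.60
#> 3    1.0      24  54.28        5.484     48.80
#> 4    1.5      34  63.15        6.718     56.44
#> 5    2.0      48  68.20        8.851     59.35

## figures
render_heatmap(build_heatmap(measurements, n_bins = 48), dest = "heatmap.pdf")
```

The corrected heterogeneity stays far above zero at every time point — the
population is genuinely heterogeneous, not just noisy at the measurement
level. For a homogeneous control series the same column scatters around zero.
The heatmap PDF shows the two intensity bands separated by an empty gap
across all frames.

The same pipeline runs from the shell via the thin wrapper in
`inst/cli/tlmquant.R` (`simulate`, `segment`, `quantify`, `fit-baseline`,
`heterogeneity`, `plot`, and `run` with a YAML config; exit codes 0/1/2 for
ok / stage failure / config error). `run_pipeline()` writes
`measurements.csv`, `frame_stats.csv`, `model.json`, `heterogeneity.csv`,
mask TIFFs, plots and a run log into the configured output directory.

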