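# motorquant

Quantification of kinesin motor activity — and its small-molecule
inhibition — from fluorescence microscopy, for cell biologists and
biophysicists who measure motor function through cellular cargo assays or
single-molecule TIRF imaging.

Kinesins are microtubule motor proteins that step processively along
filaments. Their activity can be read out at several scales, and motorquant
implements one tested pipeline for each readout:

* **Golgi dispersion** (fixed cells): active motors targeted to the Golgi
  scatter it from a perinuclear cluster. Per cell the package reports the
  Golgi integrity statistic
  `SD_i / sqrt(mean)` over the nucleus mask extended outward by 10 px —
  high for a compact Golgi, low for a dispersed one, and exactly 1 for pure
  shot noise at any exposure (the property that makes it comparable across
  staining efficiencies).
* **Inducible peroxisome redistribution** (live two-channel time lapse):
  after motors are chemically recruited to peroxisomes, organelle pixels
  move outward. Per frame: local-adaptive-threshold segmentation, mean
  object-pixel distance from the cell centre (µm), and mean recruitment
  channel intensity over object pixels.
* **Microtubule sliding** (photoconversion time lapse): bleach correction,
  per-frame motile fraction `%MF = 100 · pixels outside the initial zone /
  total microtubule pixels`, and the sliding rate as the slope of the
  best-R² initial linear segment (≥ 4 points, windows anchored at frame 1).
* **Single-molecule trajectory statistics** (TIRF tracking tables):
  lifetime ≥ 0.5 s and microtubule-overlap filtering; classification into
  motile (start-to-end run > 250 nm), immotile (run < 250 nm, dwell
  2.5–10 s) and discarded events; truncation-aware exponential fit of run
  lengths with percentile-bootstrap 95% CIs (n = 2000); event frequencies
  per µm of microtubule per minute; Welch t and Kolmogorov–Smirnov
  comparisons between ± drug conditions.
* **Neurite tip accumulation**: distal/proximal fluorescence ratio.

A synthetic-data generator (`gen_golgi_scene()`, `gen_perox_movie()`,
`gen_sliding_movie()`, `gen_trajectories()`, `gen_poisson_field()`)
produces image stacks and trajectory tables from the statistical model each
assay assumes, with every generative parameter recorded in a ground-truth
sidecar — so the entire analysis chain is verifiable end to end without any
raw microscopy data. See `vignette("motorquant-methods")` for the models,
parameter defaults and design choices.

## Worked example

Simulate one TIRF field with known ground truth (40 µm of microtubule,
5 min movie, 2.5 landings/µm/min, mean run 1200 nm, mean velocity
800 nm/s), then run the single-molecule pipeline on it:

```r
library(motorquant)

sim <- gen_trajectories(mt_length_um = 40, duration_min = 5,
                        landing_rate_per_um_min = 2.5, mean_run_nm = 1200,
                        mean_velocity_nm_s = 800, seed = 42)
tracks <- filter_tracks(sim$tset, sim$mt_mask)     # lifetime + overlap rules
events <- classify_events(tracks)                  # motile / immotile / discarded
mt_um  <- mt_total_length(sim$mt_mask, pixel_size_nm = 107)
stats  <- summarize_events(events, mt_um, duration_min = 5, seed = 1)
print(stats)
#> EventStats: 280 motile, 181 immotile over 44.6 um x 5 min
#>   freq 1.257 (motile) / 0.8122 (immotile) events/um/min
#>   mean run 1318 nm [1186, 1445], mean velocity 786 nm/s [768, 804] (boot n=2000)
```

The mean run (1318 nm, CI 1186–1445) is the truncation-corrected
exponential mean and covers the generative 1200 nm; the velocity estimate
(786 ± ~18 nm/s) recovers the generative 800 nm/s. Frequencies use the
microtubule length measured from the mask by skeletonisation (44.6 µm here:
raster chain length slightly over-measures a curved 40 µm path).

The sliding assay, end to end on a synthetic photoconversion movie:

```r
mv  <- gen_sliding_movie(rate_pct_min = 5, seed = 42)
fit <- sliding_pipeline(mv$stack)   # bleach-correct, %MF, best-R2 slope
print(fit)
#> SlidingSeries: 8 frames; rate 5.142 %/min over frames 1-8 (R2 0.997)
```

The recovered sliding rate (5.14 %MF/min) matches the generator's 5 %/min
within the granularity of the simulated schedule.

Batch execution runs through JSON configurations:
`run_assay(read_run_config("cfg.json"))` writes results plus a
`manifest.json` that reproduces the run byte-for-byte (a thin CLI wrapper
lives in `inst/cli/motorquant.R`).

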