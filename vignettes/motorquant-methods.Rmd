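---
title: "Quantifying motor activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motor activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorquant)
```

motorquant quantifies microtubule motor (kinesin) activity from fluorescence
microscopy through five independent readouts, each with its own statistical
model, plus a synthetic-data generator that produces image stacks and
trajectory tables with known ground truth. This vignette describes the model
behind each readout, the tunable parameters and their defaults, the numerical
choices made where several were defensible, and what the synthetic tests do
and do not demonstrate about real data.

## Golgi dispersion: the integrity statistic

Active motors targeted to the Golgi scatter it from a tight perinuclear
cluster into puncta spread through the cell. The readout is a per-cell scalar

$$\mathrm{integrity} = \frac{\mathrm{SD}_i}{\sqrt{\overline{I}}}$$

computed over a perinuclear measurement region: the nucleus is segmented
inside a user-supplied coarse ROI by an Otsu threshold (largest component
kept, holes filled) and extended outward by 10 pixels with an exact
Euclidean-disc dilation. A compact Golgi concentrates signal in few bright
pixels of that region, giving a high SD relative to the mean; a dispersed
Golgi leaves the region near its background, pulling the statistic down.

The $\sqrt{\overline{I}}$ normaliser is what makes the statistic comparable
across staining efficiencies and exposure times: for pure shot noise,
photon counts are Poisson, variance equals mean, and the statistic is exactly
1 whatever the intensity. `gen_poisson_field()` exists to verify this
calibration directly; the suite checks it at mean levels 25, 100 and 400.

Choices a user can revisit:

* **Population SD** (divide by $N$) is the default, with
  `sd_type = "sample"` available. The statistic is a descriptor of one
  region's histogram, not an estimator of a sampling distribution, so the
  population convention is the natural one; at typical region sizes
  (thousands of pixels) the two are indistinguishable.
* **Measurement region** defaults to the full dilated nuclear area
  (`region = "full"`); `region = "ring"` excludes the nucleus proper. The
  full area matches the described procedure; the switch exists because the
  exclusion question is a genuine ambiguity.
* The coarse nucleus ROI is an input (a polygon file in batch use) — the
  original procedure selected it manually, and automating whole-cell
  segmentation is out of scope.

The tip-accumulation ratio for neurite-bearing cells is the quotient of
background-subtracted mean fluorescence in a distal (tip) ROI over a
proximal (shaft) ROI; background subtraction defaults to off (a plain
ratio).

## Peroxisome redistribution

After chemically induced recruitment of motors to peroxisomes, organelles
move outward. Per frame, the organelle (561 nm) channel is segmented by a
local-mean adaptive threshold — pixel kept when it exceeds the mean of its
`window_px` × `window_px` neighbourhood (default 15 px) by `offset`
(default: twice a MAD-based robust background SD), components under
4 pixels dropped — and two series are reported: the mean Euclidean distance
of *all object pixels* (not centroids) from a user-given cell centre, in µm,
and the mean recruitment (488 nm) intensity over those same pixels. Empty
frames propagate as missing values, never zeros, because zeros would fake
inward motion. The outward speed is summarised as the OLS slope of distance
against time over a post-treatment window (`perox_distance_slope()`).

The adaptive-threshold parameters are package choices, not reproductions:
the original analysis cites an external local-adaptive-thresholding
implementation without recording its settings.

## Microtubule sliding

Photoconverted microtubules leave their conversion zone when slid by
kinesin-1. The pipeline is:

1. **Bleach correction** (ratio method): every frame is rescaled so its
   whole-frame mean equals frame 1's.
2. **Thresholding**: an Otsu threshold computed *on frame 1 only* and applied
   to all frames. Recomputing per frame would let residual bleaching drift
   the threshold and masquerade as motility; fixing it after bleach
   correction keeps the per-frame pixel counts comparable.
3. **Initial zone**: morphological closing of the filled convex hull of the
   frame-1 mask (or a user-supplied mask). The hull always contains its
   defining pixels, so the motile fraction of frame 1 is 0 by construction.
4. **Motile fraction** per frame:
   $\%\mathrm{MF} = 100 \cdot \mathrm{pixels}^\mathrm{outside\ zone} /
   \mathrm{pixels}^\mathrm{total}$.
5. **Rate**: over every window anchored at frame 1 with at least 4 points,
   fit OLS of %MF against time and keep the window with the highest $R^2$ —
   the initial linear section. Ties break toward the longer window (then
   determinism needs nothing further, since windows share an anchor). A
   series with zero variance gets $R^2$ defined as 0, slope 0 and the full
   window: no motion detected. The selected window is checked against
   exhaustive enumeration in the tests.

Whether the "total" pixel count should be restricted to a cell footprint is
left open in the source procedure; the whole frame is used here, which is
equivalent whenever the field contains one cell.

## Single-molecule trajectory statistics

Trajectory tables (track id, time s, x nm, y nm — the output of
single-particle tracking, which is out of scope here) are filtered and
classified:

* **Filtering**: lifetime ≥ 0.5 s and every sample on the microtubule mask
  dilated by 1 px.
* **Run length** is the Euclidean start-to-end displacement — a chord, not a
  path sum — which makes it insensitive to localization noise and therefore
  usable for slow, inhibited motors.
* **Classification**: run > 250 nm → motile; run < 250 nm with duration in
  [2.5, 10] s → immotile; anything else → discarded (sub-2.5-s dwells are
  indistinguishable from transient collisions, longer ones from nonspecific
  adsorption). Exactly 250 nm is discarded: both rules are strict
  inequalities, and the case has measure zero.
* **Frequencies**: counts per µm of microtubule per minute, with the
  microtubule length measured by Zhang–Suen skeletonisation and the
  1/√2-step convention over adjacent skeleton pixels.

**Run-length estimation under truncation.** Observed motile runs are
left-truncated at $r_\min = 250$ nm. If true runs are exponential with mean
$\mu$, memorylessness gives $\mathrm{run} - r_\min \sim \mathrm{Exp}(\mu)$,
so the maximum-likelihood estimate of the mean run length is the sample mean
of the excesses, $\hat\mu = \overline{\mathrm{run} - r_\min}$. This is the
package default (`truncation = "shifted"`) and is the quantity the
parameter-recovery tests target. The alternative `truncation = "none"`
reports the plain mean of the observed runs; for truncated data it exceeds
$\mu$ by exactly $r_\min$, and it is provided for comparison with analyses
that ignore the detection threshold. Velocities are summarised by their
sample mean (the normal-distribution fit mean); per-event velocity is run
length over duration, not a frame-to-frame instantaneous speed.

95% confidence intervals are percentile bootstrap over events with 2,000
resamples, seeded: identical inputs and seed reproduce identical intervals.

**Condition comparisons.** Per-movie frequencies ± drug are compared by
their ratio and a heteroscedastic (Welch) two-tailed t-test; per-cell rate
distributions by the two-sample Kolmogorov–Smirnov test. One calibration
subtlety: the exact small-sample KS test is conservative because the D
statistic is discrete — at 20–100 observations per group its achievable
level at nominal 5% is only ≈3–4%. The suite therefore verifies the 5%
type-I rate in the asymptotic regime (500 per group), where the level is
attained; at realistic per-cell sample sizes users should expect the KS
test to be slightly conservative, never anticonservative.

## The synthetic-data generator

Each generator draws from the statistical model its assay assumes, records
every generative parameter in a `SyntheticTruth` sidecar (JSON), and is
bit-reproducible from (seed, parameters). Spots are rendered as 2-D
Gaussians of SD 1.3 px — a point-spread-function stand-in — and Poisson
noise is always applied last, so expected intensities are exact.

* `gen_golgi_scene()`: compact scenes place 12 puncta in a crescent hugging
  the nucleus border (within the 10-px band); dispersed scenes spread the
  same expected total signal over 40 puncta uniform in the cell footprint.
  Matching totals by construction means integrity differences cannot come
  from brightness.
* `gen_perox_movie()`: puncta jitter in place (30 nm SD) until the
  treatment time, then move radially outward at the set speed, clamping at
  a cell-boundary radius; the recruitment channel ramps linearly to a
  plateau over 60 s. Defaults (24 frames at 15 s, treatment at 75 s, radii
  1–3 µm, boundary 11 µm) keep the default 20 nm/s run clamp-free for the
  whole movie.
* `gen_sliding_movie()`: curvilinear segments (bounded-curvature random
  walks) start inside a disc zone; per frame a scheduled subset is
  translocated fully outside so the true motile fraction follows
  $\min(\mathrm{rate}\cdot t, \mathrm{plateau})$, granular at
  $100/n_\mathrm{segments} = 2\%$. Both placements are rejection-sampled to
  be overlap-free, so every segment contributes the same pixel count whether
  moved or not — without this the pixel-based fraction is biased by
  differential crowding. Bleaching multiplies each frame by
  $(1-b)^{k}$ before noise.
* `gen_trajectories()`: landings are Poisson with expectation
  rate × length × duration on a piecewise-linear microtubule path; motile
  landings draw an exponential run (the landing position is conditioned so
  the run completes on the path, keeping the realized run law exactly
  exponential), a truncated-normal velocity, and are sampled every 0.1 s;
  immotile landings dwell Uniform(2.5, 10) s in place. Isotropic Gaussian
  localization noise (20 nm SD) is added per sample. Landing times are
  drawn so events complete inside the movie; censoring at movie boundaries
  is deliberately not modelled. The recorded true run is the start-to-end
  chord of the noiseless path — the quantity the analysis convention
  measures — which on a curved path sits marginally (<1%) below the
  arc-length draw.

Landing-rate magnitudes and localization noise have no authoritative
values; the defaults are chosen to give statistically comfortable event
counts at desk scale and are flagged as non-biological.

**What passing tests show, and what they do not.** The generators share the
pipelines' distributional assumptions: Gaussian spots, uniform backgrounds,
exponential runs, stationary microtubules in TIRF fields, registered frames.
Recovery of ground truth therefore validates the estimators and their
implementation — not robustness to aberrated PSFs, uneven illumination,
cell-to-cell background structure, drift (input movies are assumed
registered), motor pausing within runs, or tracking errors upstream of the
trajectory tables.

## Problem sizes and reproducibility

The test suite and the acceptance script run all simulations at reduced but
statistically meaningful sizes, chosen so each check retains clear margins:
256² shot-noise fields, 20 matched Golgi scene pairs, 15 sliding movies
(three rates × five seeds) at 384² and 8 frames, 24-frame peroxisome movies,
and trajectory sets of ≈500 landings (40 µm × 5 min × 2.5 µm⁻¹min⁻¹) with
2,000 bootstrap resamples. Every random step takes an explicit seed; the
pipeline runner `run_assay()` echoes the merged configuration into a
manifest, and re-running any pipeline from its manifest reproduces its
output files byte for byte.

## Known limitations

* No optical realism in the generators (no EMCCD gain, aberrations, or
  uneven illumination) and no 8-nm stepping — motion is smooth.
* Spot detection and track linking from raw TIRF movies are out of scope;
  the package consumes trajectory tables.
* The sliding zone estimate assumes the photoconverted region is convex;
  concave zones need a user-supplied mask.
* Whole-cell segmentation is not attempted anywhere; coarse ROIs, cell
  centres and polygon files stand in for the original manual selections.
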