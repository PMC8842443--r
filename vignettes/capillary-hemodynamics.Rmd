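---
title: "Quantifying retinal capillary hemodynamics and retinal thickness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal capillary hemodynamics and retinal thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capillux)
```

## The measurement problem

In the living mouse eye, an adaptive-optics scanning light ophthalmoscope
(AOSLO) can park its fast scanner (15.45 kHz line rate) on a single
capillary and record a space--time image, or *kymograph*: one axis is the
scanned line (space), the other is the scan index (time). Each red blood
cell (RBC) squeezing through the vessel in single file leaves a dark blob.
From these images one can count cells (flux, cells/s), time how long each
cell occupies the beam (dwell time, hence velocity), and measure how wide
the compressed cell is (the patent lumen diameter). A commercial OCT adds
total retinal thickness, segmented between the vitreous--internal limiting
membrane (ILM) boundary and the outer segment--retinal pigment epithelium
(OS--RPE) boundary. The scientific application is longitudinal: comparing
a chronically hyperglycemic (Ins2^Akita^) mouse group against euglycemic
littermates, week by week.

`capillux` implements the full quantification chain plus a synthetic-data
generator that emulates all three acquisitions with known ground truth, so
every stage is testable end to end without any instrument data.

## The flux and velocity model

Counting operates on grader-placed (or, for fixtures, automatically
detected) cell centroids in `(scan index, spatial pixel)` coordinates.

* **Per-second flux** tiles the recording into contiguous half-open
  windows of `window_s` seconds (default 1 s, the analysis convention)
  and reports `count / window_s`. A marker falling exactly on a window
  edge belongs to the later window; whether partial cells at window edges
  should count is not decidable from first principles, so the half-open
  rule was fixed once and documented.
* **Instantaneous flux** between consecutive markers is
  `scan_rate / gap_scans`, placed at the (fractional) pair midpoint.
* **Velocity** of a cell is `7.25 um / dwell_time`: compressed RBCs are
  treated as a fixed 7.25 um rod, so the only measurement is the number
  of scans the cell occupies the line.
* **Stall**: zero markers in the analysis window.
* **Quality filtering** retains capillaries graded 3--5 on the 1--5
  subjective quality index before any flux analysis.

A caution worth stating explicitly: the *mean* of instantaneous flux
equals windowed flux only for reasonably regular trains. For memoryless
(Poisson) gaps the expectation of `1/gap` diverges, so on purely random
fixtures the two statistics drift apart by construction, not by bug. The
generator therefore offers a deterministic `"warped_regular"` arrival mode
(a regular train warped through the inverse cumulative rate) for
pulsatility checks; with sinusoidal modulation of depth $d$ the
event-weighted mean rate exceeds the time average by $d^2/2$ (about 3% at
the $d = 0.25$ used in the pulsatility fixtures), which is why those
checks use a modest modulation depth.

## The synthetic kymograph

Arrivals are an inhomogeneous Poisson process with rate
$\lambda(t) = F\,(1 + d \sin 2\pi f_c t)$, $f_c \approx 4.5$ Hz emulating
the mouse heart rate; depth $d < 1$ keeps the rate positive. Rendering
adds the physics the point process lacks:

* **Single-file queueing.** Two cells cannot occupy the same stretch of
  vessel, so rendered centres are pushed to at least two dwell times
  apart (one plasma gap of about a cell length). Ground-truth markers are
  the *rendered* centroids; the arrival process itself, and its
  rate-calibration property, are untouched.
* **Geometry.** Horizontal blob extent is the dwell,
  `round(7.25 um / speed * scan_rate)` scans; vertical extent is the
  lumen projected through the vessel angle,
  `lumen / (pitch * cos(angle))` pixels. Profiles are super-Gaussian so
  the half-depth width equals the nominal extent, which is what the boxed
  width measurement reads out.
* **Eye motion** shifts the vessel band vertically scan by scan
  (sinusoid + drift); **noise** is additive Gaussian.

Defaults (64 spatial px at 0.5 um/px, 100 cells/s, lumen 4.1 um, speed
7250 um/s, noise SD 2) are one fixed choice of realistic acquisition; the
real instrument samples finer (about 0.05 um/px over a 0.71 degree line)
but that only rescales the geometry. What the fixtures do *not* model:
optical point-spread, photon noise statistics, parachute cell shapes,
inter-cell plasma gaps of varying length, or grader behaviour. Passing
tests therefore demonstrate correctness of the *computations*, not parity
with human performance on instrument data.

The bundled detector (`detect_cells_synthetic`) exists to close the loop
on fixtures: light smoothing (sigma 2 px -- the 7.5 px counting filter is
for human contrast and would merge adjacent blobs at high flux), removal
of the time-static component (per-row median, which also removes a
stalled cell's static band), Otsu threshold, 8-connected components. A
threshold that lands within six robust noise SDs of zero is read as "no
cells", which is what makes stalled and empty recordings come back empty.

## Lumen diameter

Three boxed width measures (15-ms boxes over the three earliest
non-overlapping cells, full vertical extent at half depth) are averaged,
converted to micrometres by the age-dependent pixel pitch, and corrected
by `cos(rad(angle))`. Quantisation to whole pixels bounds the round-trip
error at one pixel pitch, which the tests assert at 0--45 degrees. The
age--magnification calibration of the real instrument is not public, so
the packaged default is a clearly-labelled single-row synthetic
placeholder (34 um/degree at all ages); fixtures always carry their own
pitch and never depend on it. Whether the cosine correction is applied
before or after micrometre conversion is immaterial (scalar
multiplication commutes), but the package applies it after, on the
micrometre value.

## Eye motion

Lateral (along-the-line) retinal displacement is estimated by averaging
blocks of 16 scans into spatial profiles and registering each block to
the first by 1-D normalised cross-correlation with parabolic sub-pixel
refinement. The first block -- not a running mean -- is the reference,
keeping the estimator linear and seed-independent. Flat (zero-variance)
profiles are flagged and reported as zero shift rather than guessed.
Velocity is the first difference of displacement times the scan rate;
displacement is mean-zeroed for reporting, matching the plotted
convention.

## OCT layer segmentation

Each B-scan is a graph: pixels are nodes, each connected to its 8
neighbours, plus two virtual terminal columns (edge weight `w_min`) so
the path may start and end at any row. The axial gradient is the
intensity difference across each adjacent pixel pair, signed by the
boundary polarity (dark-to-bright for both the vitreous--ILM and the
retina--RPE transition in this reflectivity model), clamped at zero,
smoothed laterally (Gaussian, sigma 1 px -- axial structure is never
blurred, so a laterally flat boundary is still recovered exactly), and
min--max normalised per B-scan, which makes segmentation invariant to
affine intensity rescaling. Edge weights are
$w(a,b) = 2 - (g_a + g_b) + w_{\min}$: strong boundaries are cheap
corridors, and all weights stay positive as Dijkstra requires. The
adjacent-pair gradient (value on the lower pixel) gives a single-row
ridge, so noiseless fixtures are recovered with zero error.

The ILM is segmented first over the full image; the OS--RPE boundary is
then segmented with admissible rows restricted strictly below the ILM
path, which stops both paths collapsing onto the strongest edge. The
ILM-first order is a choice; it is the right one here because the
vitreous--ILM step is the strongest dark-to-bright transition in the
model (as in real OCT). A constant image has no gradient evidence and is
refused loudly, never silently segmented. Equal-cost ties are resolved by
the deterministic shortest-path implementation (same input, same output);
no randomness is involved anywhere in segmentation. A path may occupy up
to two rows of a column under 8-connectivity; the boundary row is the
per-column mean of path rows.

Thickness is `(rpe - ilm) * axial_pitch` per A-scan; B-scans stack into
an en-face cube map, repeat cubes average into the session value. Rare
mis-segmentations can be overridden per column via `review_segmentation`,
which flags the corrected columns and re-validates `ilm < rpe`.

The test suite checks the path cost against an independent
dynamic-programming oracle (and that oracle against exhaustive
enumeration of all simple paths on tiny images), boundary recovery under
multiplicative speckle up to 20%, and exact recovery of noiseless
fixtures.

## Cohort statistics

* **Hyperglycemia designation**: two consecutive weekly readings strictly
  above 250 mg/dL. "Consecutive" is read as a run of two adjacent weeks;
  the glucometer saturates at 600 mg/dL and draws are censored there.
* **Stall rate**: exact `100 k / n`; the display convention truncates to
  two decimals (9/589 prints as 1.52%), and the exact value is always
  returned alongside.
* **Group comparison**: two-tailed unpaired Student's t with pooled
  variance (the named test's assumption); Welch is available behind
  `var_equal = FALSE` but off by default. Degenerate zero-variance
  samples with equal means return p = 1; with unequal means they error.
* **Skew/kurtosis**: the adjusted Fisher--Pearson coefficient
  $\frac{n^2}{(n-1)(n-2)} m_3 / s^3$ and the bias-adjusted excess
  kurtosis (the spreadsheet SKEW/KURT conventions, which is what the
  original analysis environment computes).
* **Regression**: OLS slope with $R^2$ the squared Pearson correlation.
* **Bland--Altman**: with no gold standard for flux, the per-capillary
  grader mean is the reference; per grader, bias, +/-1.96 SD limits of
  agreement, a t-interval for the bias, and limit confidence intervals
  built from the exact two-sided normal tolerance factor
  $k(n, P{=}0.95, \gamma{=}0.95)$, computed numerically from the
  noncentral chi-square formulation (inner root for the coverage
  half-width at each standardised sample mean, outer root on the
  confidence integral). Howe's approximation is available as a fallback
  and agrees to well under 1% at these sample sizes. The outer bound of
  each limit is `bias +/- k*sd`; the inner bound is its mirror image
  about the limit. Biases across graders sum to zero exactly because the
  reference is their mean.

No multiple-testing correction is applied anywhere, deliberately
mirroring the original analysis; this is a property of the reproduction,
not a recommendation.

## The cohort generator

Group-level defaults are the published cohort values: glucose
461.51 +/- 93.74 vs 180.79 +/- 39.43 mg/dL, flux 99.85 +/- 58.53 vs
102.77 +/- 65.12 cells/s, lumen 4.2 +/- 0.6 vs 4.1 +/- 0.5 um (range
2.8--7.0), thickness 213.7 +/- 3.79 vs 221.06 +/- 5.79 um, week-to-week
flux CV 27% vs 32%, stall probability 1.5% per visit, 9 mice per group,
97 vs 86 tracked capillaries, weekly glucose/weight over weeks 5--18,
biweekly capillary sessions, 4-weekly OCT sessions averaged over two
repeat cubes.

Structural choices worth knowing:

* Hyperglycemic glucose draws are rejection-resampled above the 250
  mg/dL cutoff so designation holds by construction; truncating
  N(461.51, 93.74) at 250 shifts its mean negligibly.
* Each capillary has a persistent diameter (normal, truncated to the
  observed 2.8--7.0 um range) and a persistent mean flux drawn from a
  **gamma** distribution about a conditional mean linear in diameter
  (built-in slope 45 cells/s per um, within the published 42.9--49.5
  range). The gamma choice -- rather than a truncated normal -- keeps
  `E[flux | diameter]` exactly linear on positive support (a zero-floor
  truncated normal inflates the mean at small diameters and attenuates
  the recovered slope by about 20%) and produces the mild positive skew
  seen in the flux distribution. The residual SD is set so the
  population SD matches the published group SD after adding the
  within-capillary CV.
* Thickness sessions are independent draws at the published group
  mean/SD, i.e. the printed SD is treated as session-level scatter; the
  group contrast is then tested on all sessions, matching the pooled
  cube-level test of the original analysis.
* Glucose, weight and thickness draws are independent across weeks
  within a mouse -- real longitudinal autocorrelation is *not* modelled,
  so the generator supports group-level calibration checks, not
  within-mouse trajectory inference.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use 1-s kymographs (15 450
scans by 64 px), B-scans of 64--96 columns by 120--160 rows, 15--50 seeds
per recovery curve, and 60--100 seeds for stochastic proportions. These
sizes were chosen so the entire verification runs in a few minutes on one
CPU while keeping every standard error small enough for the stated
tolerances; all of them scale up by changing parameters only.

## Known limitations

* The detector is a fixture tool, not a grader model; no claim is made
  about human-grade counting on instrument data.
* Vessel angle is an input (measured from Cartesian images in the real
  protocol); the package does not estimate it.
* Only total retinal thickness is segmented -- intermediate layers are
  out of scope, as is motion correction between B-scans.
* The exact tolerance-factor construction in the published figures is
  not specified to the third decimal; ours is the standard exact
  formulation and may differ in that digit.
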