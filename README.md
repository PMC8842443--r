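# capillux

Quantification of retinal capillary hemodynamics and retinal thickness in
the living mouse eye, with a fully synthetic test bench.

Adaptive-optics line-scan ophthalmoscopy can hold a 15.45 kHz scanner on a
single capillary and record a space–time image (kymograph) in which every
red blood cell (RBC) leaves a dark blob. `capillux` implements the complete
measurement chain for such recordings and for companion OCT volumes, aimed
at researchers studying retinal microvasculature (for example, longitudinal
comparisons of hyperglycemic Ins2^Akita^ mice against euglycemic
littermates):

- **RBC flux** — per-second flux over tiled 1-s windows; instantaneous
  flux between marker pairs, `Flux_i = scan_rate / gap_scans`; cumulative
  mean ± SD traces; stall detection (zero flux in the window); quality-index
  filtering (grades 3–5 analysed).
- **RBC velocity** — `V_i = 7.25 µm / dwell_time`, the compressed-cell
  length over the time a cell occupies the beam.
- **Lumen diameter** — mean of three boxed (15 ms) RBC width measures,
  age-scaled pixel pitch, and vessel-angle correction `cos(rad(θ))`;
  capillaries are vessels < 7 µm.
- **Eye motion** — 1-D normalized cross-correlation registration of
  block-averaged line profiles with sub-pixel refinement; velocity =
  displacement increment × scan rate.
- **OCT thickness** — each B-scan becomes an 8-connected pixel graph with
  gradient-based edge weights `2 − (g_a + g_b) + w_min`; Dijkstra's
  shortest path traces the vitreous–ILM and OS–RPE boundaries, and
  thickness is `(rpe − ilm) × axial_pitch`, averaged per cube and session.
- **Cohort statistics** — hyperglycemia designation (consecutive weekly
  readings > 250 mg/dL, meter capped at 600), stall rates, adjusted
  Fisher–Pearson skew and excess kurtosis, pooled-variance Student t
  comparisons, OLS slope/R², and Bland–Altman grader agreement with exact
  two-sided tolerance-factor confidence intervals for the limits of
  agreement.
- **Synthetic data** — cardiac-modulated arrival processes, rendered
  kymographs with single-file queueing and eye motion, speckled B-scans,
  and a longitudinal two-group cohort generator parameterised by the
  published group means and SDs — all with known ground truth.

## Worked example

```r
library(capillux)

# a 1-s capillary recording at ~100 cells/s with known ground truth
p   <- kymo_sim_params(mean_flux_cells_s = 100, seed = 42)
sim <- simulate_kymograph(p)
sim$kymo
#> <kymograph> 64 px x 15450 scans @ 15450 Hz (1.000 s), 0.5 um/px

flux_per_second(sim$markers, p$scan_rate_hz,
                n_scans = ncol(sim$kymo$image))
#> [1] 120
nrow(detect_cells_synthetic(sim$kymo))   # automated recount
#> [1] 120
cell_velocity(15, p$scan_rate_hz)        # a 15-scan dwell
#> [1] 7467.5

# OCT: segment a speckled B-scan and measure thickness
b   <- simulate_bscan(oct_sim_params(speckle_sd = 0.1, seed = 7))
seg <- segment_bscan(b$bscan)
total_retinal_thickness(seg)$mean_um
#> [1] 220
mean(b$thickness_true_um)
#> [1] 220

# cohort: retinal thickness contrast at the default study conditions
co <- simulate_cohort(cohort_sim_params(seed = 1))
th <- split(co$thickness$thickness_um, co$thickness$group)
group_compare(th$hyperglycemic, th$euglycemic)
#> group A: 214.48 +/- 3.26 (n=36)
#> group B: 221.11 +/- 5.85 (n=36)
#> t = -5.944, two-tailed p = 9.82e-08
```

The per-second flux (120 cells/s) is the exact marker count of this
realisation — the nominal 100 cells/s is the process mean, and the
automated detector recovers every rendered cell. The thickness comparison
shows the thinner hyperglycemic retina that the cohort generator builds in
(213.7 vs 221.06 µm group means) reaching significance on 36 sessions per
group.

## Analysis workflow

Numbered drivers under `analysis/` run the study end to end on synthetic
data and write tables under `results/`:

1. `01_simulate_cohort.R` — cohort tables, weekly glucose summary,
   designation check.
2. `02_kymograph_flux.R` — flux recovery across 25/100/400 cells/s.
3. `03_diameter_eyemotion.R` — diameter round trip at 0–45°, eye-motion
   registration.
4. `04_oct_thickness.R` — cube segmentation, session averaging.
5. `05_cohort_statistics.R` — group descriptives, stall rates,
   regressions, Bland–Altman.

`run_pipeline(run_config(seed = 1))` performs a bundled run with
provenance (config hash embedded in the outputs).

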