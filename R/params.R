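#' Simulation parameters for a capillary line-scan (kymograph) recording
#'
#' Bundles the acquisition geometry and physiology of a single-file
#' capillary line scan: a fast scanner repeatedly samples one line across a
#' vessel, producing a space-time image in which each passing red blood
#' cell (RBC) leaves a dark blob. Defaults mirror the study acquisition:
#' 15.45 kHz line rate, 7.25 um compressed RBC length, capillary lumen
#' under 7 um.
#'
#' @param duration_s recording duration in seconds (> 0).
#' @param scan_rate_hz line-scan rate in scans/s. Must exceed twice
#'   `mean_flux_cells_s` (temporal Nyquist for counting cells).
#' @param n_space_px number of spatial pixels along the scanned line.
#' @param pixel_pitch_um spatial sampling along the line, um/pixel.
#' @param mean_flux_cells_s mean RBC flux of the simulated capillary,
#'   cells/s. Zero gives a cell-free (but not stalled) recording.
#' @param cardiac_freq_hz cardiac modulation frequency, Hz (mouse heart
#'   rate, roughly 4-5 Hz).
#' @param cardiac_mod_depth fractional depth of the sinusoidal cardiac
#'   modulation of flux, in `[0, 1)`.
#' @param rbc_length_um compressed RBC length, um (fixed at 7.25 in the
#'   downstream velocity computation).
#' @param lumen_diameter_um patent lumen diameter, um; must be < 7
#'   (definition of a capillary).
#' @param vessel_angle_deg angle of the vessel from vertical (the scanned
#'   line), degrees in `[0, 90)`.
#' @param rbc_speed_um_s RBC speed along the vessel, um/s.
#' @param stall logical; a stalled capillary renders a static dark band
#'   and produces no cell passages.
#' @param noise_sd additive Gaussian intensity noise SD (image intensity
#'   units on a 0-255 scale).
#' @param eye_motion an [eye_motion_params()] object.
#' @param seed integer seed making the simulation reproducible.
#'
#' @return A validated list of class `kymo_sim_params`.
#' @seealso [simulate_arrival_times()], [render_kymograph()]
#' @export
kymo_sim_params <- function(duration_s = 1,
                            scan_rate_hz = 15450,
                            n_space_px = 64,
                            pixel_pitch_um = 0.5,
                            mean_flux_cells_s = 100,
                            cardiac_freq_hz = 4.5,
                            cardiac_mod_depth = 0.3,
                            rbc_length_um = 7.25,
                            lumen_diameter_um = 4.1,
                            vessel_angle_deg = 0,
                            rbc_speed_um_s = 7250,
                            stall = FALSE,
                            noise_sd = 2,
                            eye_motion = eye_motion_params(),
                            seed = NULL) {
  stopifnot(duration_s > 0, scan_rate_hz > 0, n_space_px >= 2,
            pixel_pitch_um > 0, mean_flux_cells_s >= 0,
            cardiac_freq_hz >= 0, rbc_length_um > 0,
            rbc_speed_um_s > 0, noise_sd >= 0)
  if (cardiac_mod_depth < 0 || cardiac_mod_depth >= 1)
    stop("cardiac_mod_depth must lie in [0, 1): a depth >= 1 makes the ",
         "arrival rate negative over part of the cardiac cycle")
  if (scan_rate_hz <= 2 * mean_flux_cells_s)
    stop("scan_rate_hz must exceed twice mean_flux_cells_s (Nyquist)")
  if (lumen_diameter_um <= 0 || lumen_diameter_um >= 7)
    stop("lumen_diameter_um must be in (0, 7): capillaries are defined as ",
         "vessels less than 7 um in diameter")
  if (vessel_angle_deg < 0 || vessel_angle_deg >= 90)
    stop("vessel_angle_deg must lie in [0, 90)")
  stopifnot(inherits(eye_motion, "eye_motion_params"))
  structure(list(duration_s = duration_s, scan_rate_hz = scan_rate_hz,
                 n_space_px = n_space_px, pixel_pitch_um = pixel_pitch_um,
                 mean_flux_cells_s = mean_flux_cells_s,
                 cardiac_freq_hz = cardiac_freq_hz,
                 cardiac_mod_depth = cardiac_mod_depth,
                 rbc_length_um = rbc_length_um,
                 lumen_diameter_um = lumen_diameter_um,
                 vessel_angle_deg = vessel_angle_deg,
                 rbc_speed_um_s = rbc_speed_um_s,
                 stall = isTRUE(stall), noise_sd = noise_sd,
                 eye_motion = eye_motion, seed = seed),
            class = "kymo_sim_params")
}

#' Eye-motion parameters for the kymograph simulator
#'
#' Lateral (along the scanned line) retinal displacement is modelled as a
#' sinusoid plus linear drift; zero amplitude and drift disable motion.
#'
#' @param amplitude_um sinusoid amplitude, um (>= 0).
#' @param freq_hz sinusoid frequency, Hz.
#' @param drift_um_s linear drift rate, um/s.
#' @param phase_rad phase of the sinusoid at scan 0, radians.
#' @return A list of class `eye_motion_params`.
#' @export
eye_motion_params <- function(amplitude_um = 0, freq_hz = 1,
                              drift_um_s = 0, phase_rad = 0) {
  stopifnot(amplitude_um >= 0, freq_hz >= 0)
  structure(list(amplitude_um = amplitude_um, freq_hz = freq_hz,
                 drift_um_s = drift_um_s, phase_rad = phase_rad),
            class = "eye_motion_params")
}

#' Simulation parameters for an OCT B-scan
#'
#' Describes a piecewise-constant axial reflectivity model: dark vitreous
#' above the internal limiting membrane (ILM), moderately bright retina
#' between the ILM and the outer segment-retinal pigment epithelium
#' (OS-RPE) boundary, a brighter RPE band, and dark choroid/sclera below,
#' degraded by multiplicative speckle.
#'
#' @param n_cols number of A-scans (lateral pixels).
#' @param n_rows number of axial pixels.
#' @param axial_pitch_um axial sampling, um/pixel.
#' @param ilm_profile,rpe_profile per-column boundary rows (1-based, may be
#'   scalar and is then recycled); must satisfy `0 < ilm < rpe <= n_rows`
#'   columnwise.
#' @param layer_contrast intensity step scale (arbitrary units).
#' @param speckle_sd multiplicative speckle SD as a fraction of local
#'   intensity.
#' @param rpe_band_px thickness of the bright RPE band, pixels.
#' @param seed integer seed.
#' @return A validated list of class `oct_sim_params`.
#' @export
oct_sim_params <- function(n_cols = 96, n_rows = 160, axial_pitch_um = 2,
                           ilm_profile = 30, rpe_profile = 140,
                           layer_contrast = 100, speckle_sd = 0.1,
                           rpe_band_px = 8, seed = NULL) {
  stopifnot(n_cols >= 2, n_rows >= 2, axial_pitch_um > 0,
            layer_contrast > 0, speckle_sd >= 0, rpe_band_px >= 1)
  ilm <- rep_len(ilm_profile, n_cols)
  rpe <- rep_len(rpe_profile, n_cols)
  if (any(ilm <= 0) || any(rpe <= ilm) || any(rpe > n_rows))
    stop("boundary profiles must satisfy 0 < ilm_row < rpe_row <= n_rows ",
         "in every column")
  structure(list(n_cols = n_cols, n_rows = n_rows,
                 axial_pitch_um = axial_pitch_um,
                 ilm_profile = ilm, rpe_profile = rpe,
                 layer_contrast = layer_contrast, speckle_sd = speckle_sd,
                 rpe_band_px = rpe_band_px, seed = seed),
            class = "oct_sim_params")
}

#' Simulation parameters for the longitudinal mouse cohort
#'
#' Group-level means and SDs default to the published cohort values:
#' weekly blood glucose 461.51 +/- 93.74 mg/dL (hyperglycemic, meter
#' capped at 600) vs 180.79 +/- 39.43 mg/dL (euglycemic); capillary RBC
#' flux 99.85 +/- 58.53 vs 102.77 +/- 65.12 cells/s; lumen diameter
#' 4.2 +/- 0.6 vs 4.1 +/- 0.5 um; total retinal thickness 213.7 +/- 3.79
#' vs 221.06 +/- 5.79 um; week-to-week capillary flux CV 27% vs 32%;
#' stall probability 1.5% per capillary visit.
#'
#' @param n_mice_per_group mice per group (default 9).
#' @param weeks postnatal weeks with weekly glucose/weight records.
#' @param capillary_weeks postnatal weeks with capillary line-scan
#'   sessions (biweekly by default).
#' @param thickness_weeks postnatal weeks with OCT sessions (4-weekly).
#' @param glucose_eu_mean_sd,glucose_hy_mean_sd glucose mean/SD, mg/dL.
#' @param glucose_cap glucometer saturation, mg/dL.
#' @param glucose_cutoff hyperglycemia designation cutoff, mg/dL.
#' @param flux_mean_sd_eu,flux_mean_sd_hy population flux mean/SD, cells/s.
#' @param diam_mean_sd_eu,diam_mean_sd_hy lumen diameter mean/SD, um.
#' @param diam_range admissible diameter range, um (population range of
#'   measured capillaries).
#' @param flux_diam_slope built-in flux-diameter association,
#'   cells/s per um of lumen.
#' @param week_to_week_cv_eu,week_to_week_cv_hy within-capillary
#'   week-to-week coefficient of variation (fraction of the capillary
#'   mean).
#' @param stall_prob probability that a capillary visit finds the vessel
#'   stalled (zero flux).
#' @param thickness_mean_sd_eu,thickness_mean_sd_hy session-level total
#'   retinal thickness mean/SD, um.
#' @param weight_mean_sd_eu,weight_mean_sd_hy body-weight mean/SD, g.
#' @param n_capillaries_eu,n_capillaries_hy unique tracked capillaries per
#'   group.
#' @param p_session_observed_eu,p_session_observed_hy probability a
#'   capillary yields a countable line scan at a given session (missed
#'   sessions and unusable scans).
#' @param qi_probs_eu,qi_probs_hy quality-index (1-5) marginals; defaults
#'   retain 97.3% / 95.4% of scans at QI >= 3.
#' @param seed integer seed.
#' @return A validated list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_mice_per_group = 9,
                              weeks = 5:18,
                              capillary_weeks = seq(5, 17, by = 2),
                              thickness_weeks = seq(4, 16, by = 4),
                              glucose_eu_mean_sd = c(180.79, 39.43),
                              glucose_hy_mean_sd = c(461.51, 93.74),
                              glucose_cap = 600,
                              glucose_cutoff = 250,
                              flux_mean_sd_eu = c(102.77, 65.12),
                              flux_mean_sd_hy = c(99.85, 58.53),
                              diam_mean_sd_eu = c(4.1, 0.5),
                              diam_mean_sd_hy = c(4.2, 0.6),
                              diam_range = c(2.8, 7.0),
                              flux_diam_slope = 45,
                              week_to_week_cv_eu = 0.32,
                              week_to_week_cv_hy = 0.27,
                              stall_prob = 0.015,
                              thickness_mean_sd_eu = c(221.06, 5.79),
                              thickness_mean_sd_hy = c(213.7, 3.79),
                              weight_mean_sd_eu = c(24.80, 3.87),
                              weight_mean_sd_hy = c(23.45, 3.53),
                              n_capillaries_eu = 97,
                              n_capillaries_hy = 86,
                              p_session_observed_eu = 0.87,
                              p_session_observed_hy = 0.73,
                              qi_probs_eu = c(0.010, 0.017, 0.25, 0.41, 0.313),
                              qi_probs_hy = c(0.018, 0.028, 0.26, 0.40, 0.294),
                              seed = NULL) {
  pairs <- list(glucose_eu_mean_sd, glucose_hy_mean_sd, flux_mean_sd_eu,
                flux_mean_sd_hy, diam_mean_sd_eu, diam_mean_sd_hy,
                thickness_mean_sd_eu, thickness_mean_sd_hy,
                weight_mean_sd_eu, weight_mean_sd_hy)
  if (any(vapply(pairs, length, 1L) != 2L) ||
      any(vapply(pairs, function(p) p[2] < 0, TRUE)))
    stop("mean/SD parameters must be length-2 vectors with SD >= 0")
  stopifnot(n_mice_per_group >= 1, length(weeks) >= 2,
            glucose_cap > glucose_cutoff, stall_prob >= 0, stall_prob <= 1,
            flux_diam_slope >= 0, diam_range[1] < diam_range[2],
            n_capillaries_eu >= 1, n_capillaries_hy >= 1,
            p_session_observed_eu > 0, p_session_observed_eu <= 1,
            p_session_observed_hy > 0, p_session_observed_hy <= 1,
            length(qi_probs_eu) == 5, length(qi_probs_hy) == 5,
            abs(sum(qi_probs_eu) - 1) < 1e-8,
            abs(sum(qi_probs_hy) - 1) < 1e-8)
  structure(list(n_mice_per_group = n_mice_per_group, weeks = weeks,
                 capillary_weeks = capillary_weeks,
                 thickness_weeks = thickness_weeks,
                 glucose_eu_mean_sd = glucose_eu_mean_sd,
                 glucose_hy_mean_sd = glucose_hy_mean_sd,
                 glucose_cap = glucose_cap, glucose_cutoff = glucose_cutoff,
                 flux_mean_sd_eu = flux_mean_sd_eu,
                 flux_mean_sd_hy = flux_mean_sd_hy,
                 diam_mean_sd_eu = diam_mean_sd_eu,
                 diam_mean_sd_hy = diam_mean_sd_hy,
                 diam_range = diam_range, flux_diam_slope = flux_diam_slope,
                 week_to_week_cv_eu = week_to_week_cv_eu,
                 week_to_week_cv_hy = week_to_week_cv_hy,
                 stall_prob = stall_prob,
                 thickness_mean_sd_eu = thickness_mean_sd_eu,
                 thickness_mean_sd_hy = thickness_mean_sd_hy,
                 weight_mean_sd_eu = weight_mean_sd_eu,
                 weight_mean_sd_hy = weight_mean_sd_hy,
                 n_capillaries_eu = n_capillaries_eu,
                 n_capillaries_hy = n_capillaries_hy,
                 p_session_observed_eu = p_session_observed_eu,
                 p_session_observed_hy = p_session_observed_hy,
                 qi_probs_eu = qi_probs_eu, qi_probs_hy = qi_probs_hy,
                 seed = seed),
            class = "cohort_sim_params")
}

# Run expr under a fixed seed when one is supplied, without disturbing the
# caller's RNG state; otherwise use the ambient RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
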