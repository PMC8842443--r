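test_that("parameter validation rejects unphysical settings", {
  expect_error(kymo_sim_params(cardiac_mod_depth = 1), "mod_depth")
  expect_error(kymo_sim_params(cardiac_mod_depth = 1.5), "mod_depth")
  expect_error(kymo_sim_params(lumen_diameter_um = 7.2), "less than 7")
  expect_error(kymo_sim_params(mean_flux_cells_s = 8000,
                               scan_rate_hz = 15450), "Nyquist")
  expect_error(kymo_sim_params(vessel_angle_deg = 95), "90")
  expect_error(oct_sim_params(ilm_profile = 150, rpe_profile = 140),
               "ilm_row < rpe_row")
  expect_error(cohort_sim_params(glucose_eu_mean_sd = c(100, -1)),
               "SD")
})

test_that("arrival process is calibrated to the mean flux", {
  # unmodulated 10-s draw: count within 3 SD of 1000
  p <- kymo_sim_params(duration_s = 10, mean_flux_cells_s = 100,
                       cardiac_mod_depth = 0, seed = 42)
  n <- length(simulate_arrival_times(p))
  expect_lt(abs(n - 1000), 3 * sqrt(1000))
  expect_identical(
    simulate_arrival_times(kymo_sim_params(mean_flux_cells_s = 0)),
    numeric())
  # per-second counts averaged over many seeds match the rate to 3 SE
  counts <- vapply(1:150, function(s) {
    length(simulate_arrival_times(
      kymo_sim_params(duration_s = 1, mean_flux_cells_s = 100,
                      seed = s)))
  }, 1)
  se <- sqrt(100) / sqrt(150)
  expect_lt(abs(mean(counts) - 100), 3 * se)
})

test_that("cardiac modulation shows up at the right frequency", {
  p <- kymo_sim_params(duration_s = 10, mean_flux_cells_s = 100,
                       cardiac_mod_depth = 0.5, cardiac_freq_hz = 4.5,
                       seed = 8)
  a <- simulate_arrival_times(p)
  expect_lt(abs(oracle_peak_freq(a, p$scan_rate_hz, 10) - 4.5), 0.5)
  a2 <- simulate_arrival_times(p, process = "warped_regular")
  expect_lt(abs(oracle_peak_freq(a2, p$scan_rate_hz, 10) - 4.5), 0.5)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  p <- kymo_sim_params(seed = 99)
  expect_identical(simulate_arrival_times(p), simulate_arrival_times(p))
  s1 <- simulate_kymograph(p)
  s2 <- simulate_kymograph(p)
  expect_identical(s1$kymo$image, s2$kymo$image)
  expect_identical(s1$markers$scan_index, s2$markers$scan_index)
  co1 <- simulate_cohort(cohort_sim_params(seed = 5))
  co2 <- simulate_cohort(cohort_sim_params(seed = 5))
  expect_identical(co1$capillaries, co2$capillaries)
})

test_that("renderer geometry matches the acquisition model", {
  # dwell arithmetic: 7.25 um at 7250 um/s sampled at 15450 Hz
  p <- kymo_sim_params()
  expect_true(capillux:::dwell_scans_for(p) %in% c(15L, 16L))
  expect_equal(capillux:::dwell_scans_for(p), round(7.25 / 7250 * 15450))

  # noiseless single cell: one blob, centroid at the arrival scan
  p1 <- kymo_sim_params(noise_sd = 0, mean_flux_cells_s = 5, seed = 1)
  out <- render_kymograph(7000, p1)
  det <- detect_cells_synthetic(out$kymo)
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$scan_index - 7000), 2)

  # stalled vessel: static dark band, no markers
  st <- simulate_kymograph(kymo_sim_params(stall = TRUE, seed = 2))
  expect_identical(nrow(st$markers), 0L)
  band_var <- apply(st$kymo$image, 1, stats::sd)
  expect_lt(max(band_var), 3 * 2)  # only read noise varies in time

  # marker count equals arrival count when nothing is clipped
  p2 <- kymo_sim_params(mean_flux_cells_s = 25, seed = 3)
  a <- simulate_arrival_times(p2)
  expect_identical(nrow(render_kymograph(a, p2)$markers), length(a))

  # vessel band wider than the image is rejected
  expect_error(
    render_kymograph(numeric(),
                     kymo_sim_params(n_space_px = 8,
                                     lumen_diameter_um = 6,
                                     pixel_pitch_um = 0.5)),
    "exceeds")
})

test_that("simulated B-scans carry their stated ground truth", {
  # noiseless flat profiles: identical columns, gradient maxima at truth
  p <- oct_sim_params(speckle_sd = 0, ilm_profile = 40,
                      rpe_profile = 150, axial_pitch_um = 2)
  sim <- simulate_bscan(p)
  img <- sim$bscan$image
  expect_true(all(img == img[, 1]))
  g <- oracle_gradient(img)
  ridge <- apply(g, 2, which.max)
  expect_true(all(ridge == 40))
  expect_equal(sim$thickness_true_um, rep(220, p$n_cols))

  # sinusoidal ILM: gradient ridge follows the sinusoid
  ilm <- round(40 + 8 * sin(2 * pi * seq_len(96) / 96))
  sim2 <- simulate_bscan(oct_sim_params(speckle_sd = 0,
                                        ilm_profile = ilm,
                                        rpe_profile = 150))
  ridge2 <- apply(oracle_gradient(sim2$bscan$image), 2, which.max)
  expect_true(all(ridge2 == ilm))

  # thickness truth is exactly (rpe - ilm) * pitch
  expect_equal(sim2$thickness_true_um, (150 - ilm) * 2)
})

test_that("cohort simulator honours caps, stalls and designations", {
  # censoring: degenerate hyperglycemic draw at the meter cap
  p <- cohort_sim_params(glucose_hy_mean_sd = c(600, 0), seed = 1,
                         n_mice_per_group = 2)
  co <- simulate_cohort(p)
  hy <- co$mice$glucose_mgdl[co$mice$group == "hyperglycemic"]
  expect_true(all(hy == 600))

  # no stalls when stall_prob = 0
  co0 <- simulate_cohort(cohort_sim_params(stall_prob = 0, seed = 2,
                                           n_mice_per_group = 3))
  expect_false(any(co0$capillaries$stalled))

  # every hyperglycemic mouse designated, no euglycemic mouse is
  co1 <- simulate_cohort(cohort_sim_params(seed = 3))
  des <- vapply(split(co1$mice, co1$mice$mouse_id), function(df)
    designate_hyperglycemic(df$glucose_mgdl[order(df$week)]), TRUE)
  expect_true(all(des[grepl("^hy", names(des))]))
  expect_false(any(des[grepl("^eu", names(des))]))
})

test_that("cohort simulator reproduces the published group statistics", {
  co <- simulate_cohort(cohort_sim_params(seed = 7))
  gl <- split(co$mice$glucose_mgdl, co$mice$group)
  # group glucose means within 2 SE of 461.51 / 180.79 mg/dL
  expect_lt(abs(mean(gl$euglycemic) - 180.79),
            2 * 39.43 / sqrt(length(gl$euglycemic)))
  expect_lt(abs(mean(gl$hyperglycemic) - 461.51),
            2 * 93.74 / sqrt(length(gl$hyperglycemic)))
  th <- split(co$thickness$thickness_um, co$thickness$group)
  expect_lt(abs(mean(th$euglycemic) - 221.06),
            2 * 5.79 / sqrt(length(th$euglycemic)))
  expect_lt(abs(mean(th$hyperglycemic) - 213.7),
            2 * 3.79 / sqrt(length(th$hyperglycemic)))
})
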