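make_markers <- function(scans, ...) {
  cell_marker_set(scan_index = scans,
                  space_px = rep(32, length(scans)), ...)
}

test_that("spatiotemporal Gaussian filter behaves like a smoother", {
  img <- matrix(runif(64 * 200, 100, 200), 64, 200)
  k <- kymograph(img, 15450, 0.5)
  expect_identical(preprocess_kymograph(k, 0)$image, img)

  cst <- kymograph(matrix(7, 64, 200), 15450, 0.5)
  sm <- preprocess_kymograph(cst, 7.5)$image
  expect_equal(sm, matrix(7, 64, 200), tolerance = 1e-10)

  # single bright pixel in a constant-padded interior: total conserved
  imp <- matrix(0, 101, 101); imp[51, 51] <- 1
  smi <- preprocess_kymograph(kymograph(imp, 15450, 0.5), 7.5)$image
  expect_lt(max(smi), 1)                    # peak reduced
  expect_lt(abs(sum(smi) - 1), 1e-6)        # mass conserved (interior)
  # metadata untouched
  expect_identical(preprocess_kymograph(k, 7.5)$scan_rate_hz, 15450)
})

test_that("per-second flux counts markers in half-open tiled windows", {
  m <- make_markers(seq(0, 15449, length.out = 100))
  expect_equal(flux_per_second(m, 15450, n_scans = 15450), 100)
  expect_equal(flux_per_second(cell_marker_set(), 15450,
                               n_scans = 15450), 0)
  expect_identical(flux_per_second(cell_marker_set(), 15450), numeric())
  expect_equal(flux_per_second(make_markers(c(0, 7725, 15449)), 15450,
                               n_scans = 15450), 3)
  # half-open convention: marker on the edge belongs to the later window
  m2 <- make_markers(c(0, 15450, 15451))
  expect_equal(flux_per_second(m2, 15450, n_scans = 2 * 15450), c(1, 2))
  # time-origin shift leaves flux unchanged
  m3 <- make_markers(seq(100, 14000, by = 200))
  shifted <- make_markers(seq(100, 14000, by = 200) + 30900)
  expect_equal(flux_per_second(m3, 15450, n_scans = 15450),
               flux_per_second(shifted, 15450, n_scans = 3 * 15450,
                               t0_scan = 30900))
})

test_that("instantaneous flux is scan rate over the marker gap", {
  m <- make_markers(c(0, 154))
  expect_equal(instantaneous_flux(m, 15450)$flux_cells_s, 15450 / 154)
  expect_equal(instantaneous_flux(make_markers(c(0, 15450)),
                                  15450)$flux_cells_s, 1)
  expect_equal(instantaneous_flux(m, 15450)$midpoint_scan, 77)
  expect_error(instantaneous_flux(make_markers(c(5, 5, 9)), 15450),
               "coincident")
  expect_error(instantaneous_flux(make_markers(7), 15450), "2 markers")
  # equally spaced trains give exactly rate/k everywhere
  for (k in c(10, 154, 1545)) {
    tr <- make_markers(seq(0, 15450, by = k))
    expect_true(all(instantaneous_flux(tr, 15450)$flux_cells_s ==
                      15450 / k))
    # and agree with the windowed per-second flux up to edge rounding
    fps <- flux_per_second(tr, 15450, n_scans = 15450)
    expect_lt(abs(mean(instantaneous_flux(tr, 15450)$flux_cells_s) -
                    fps) / fps, 0.01 + 1 / (15450 / k))
  }
})

test_that("cumulative flux statistics summarise the running trace", {
  cs <- cumulative_flux_stats(rep(42, 10))
  expect_equal(cs$cumulative_mean, rep(42, 10))
  expect_equal(cs$cumulative_sd, rep(0, 10))
  cs2 <- cumulative_flux_stats(c(100, 200))
  expect_equal(cs2$cumulative_mean, c(100, 150))
  expect_equal(cs2$cumulative_sd, c(0, stats::sd(c(100, 200))))
  expect_error(cumulative_flux_stats(numeric()), "at least one")

  # pulsatile train: cumulative mean converges to the mean rate
  p <- kymo_sim_params(duration_s = 2, mean_flux_cells_s = 100,
                       cardiac_mod_depth = 0.25, cardiac_freq_hz = 4.5)
  a <- simulate_arrival_times(p, "warped_regular")
  m <- make_markers(a)
  cm <- cumulative_flux_stats(instantaneous_flux(m, p$scan_rate_hz))
  after4 <- cm$cumulative_mean[
    instantaneous_flux(m, p$scan_rate_hz)$midpoint_scan >
      4 / 4.5 * p$scan_rate_hz]
  expect_true(all(abs(after4 - 100) / 100 < 0.05))
})

test_that("dwell-time velocity follows V = length / dwell", {
  expect_equal(cell_velocity(15450, 15450), 7.25)
  expect_equal(cell_velocity(15, 15450), 7.25 * 15450 / 15)
  expect_equal(cell_velocity(15, 15450), 7467.5)
  # inverse proportionality
  expect_equal(cell_velocity(30, 15450), cell_velocity(15, 15450) / 2)
  expect_error(cell_velocity(0, 15450), "dwell")
})

test_that("stall detection is zero flux in the analysis window", {
  expect_true(detect_stall(cell_marker_set()))
  expect_false(detect_stall(make_markers(100)))
  expect_true(detect_stall(make_markers(100), window_scans = c(200, 500)))
  # noiseless stalled fixtures detected via the synthetic detector
  for (s in 1:5) {
    sim <- simulate_kymograph(kymo_sim_params(stall = TRUE, noise_sd = 0,
                                              seed = s))
    expect_true(detect_stall(detect_cells_synthetic(sim$kymo)))
  }
})

test_that("quality-index filtering keeps grades at or above threshold", {
  rec <- data.frame(id = 1:5, quality_index = 1:5)
  expect_identical(filter_by_quality(rec)$quality_index, 3:5)
  expect_identical(filter_by_quality(rec, min_qi = 1), rec)
  expect_error(filter_by_quality(data.frame(id = 1)), "quality_index")
  # simulated QI marginals reproduce the ~96% retention of 1029 scans
  withr::with_seed(11, {
    qi <- c(sample.int(5, 589, TRUE, prob = c(0.010, 0.017, 0.25, 0.41,
                                              0.313)),
            sample.int(5, 440, TRUE, prob = c(0.018, 0.028, 0.26, 0.40,
                                              0.294)))
  })
  kept <- filter_by_quality(data.frame(quality_index = qi))
  expect_lt(abs(nrow(kept) / 1029 - 0.965), 0.02)
})

test_that("synthetic detector recovers flux from rendered fixtures", {
  for (fl in c(25, 100)) {
    sim <- simulate_kymograph(kymo_sim_params(mean_flux_cells_s = fl,
                                              seed = fl))
    det <- detect_cells_synthetic(sim$kymo)
    truth <- nrow(sim$markers)
    expect_lt(abs(nrow(det) - truth) / truth, 0.05)
    # Nyquist sanity: nothing detected above half the scan rate
    expect_lt(nrow(det), 15450 / 2)
  }
  expect_identical(
    nrow(detect_cells_synthetic(
      simulate_kymograph(kymo_sim_params(mean_flux_cells_s = 0,
                                         seed = 1))$kymo)), 0L)
})
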