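#' Configuration for an end-to-end synthetic run
#'
#' All defaults equal the study's stated analysis parameters: counting
#' filter sigma 7.5 px, 1-s flux windows, 15450 Hz scan rate, quality
#' index >= 3, 7.25 um RBC length, 600 mg/dL glucometer cap, 250 mg/dL
#' hyperglycemia cutoff.
#'
#' @param seed master seed for the run.
#' @param stages character subset of `c("cohort", "kymo", "oct")`.
#' @param out_dir output directory (created if missing).
#' @param sigma_px counting-filter sigma, pixels.
#' @param window_s flux window, seconds.
#' @param scan_rate_hz line rate, Hz.
#' @param min_qi minimum quality index analysed.
#' @param rbc_length_um compressed RBC length, um.
#' @param block_scans registration block, scans.
#' @param w_min segmentation edge-weight floor.
#' @param n_kymo_fixtures kymograph fixtures rendered in the kymo stage.
#' @param cohort_params a [cohort_sim_params()]; its seed is overridden
#'   by `seed`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(seed = 1, stages = c("cohort", "kymo", "oct"),
                       out_dir = tempfile("capillux_run_"),
                       sigma_px = 7.5, window_s = 1,
                       scan_rate_hz = 15450, min_qi = 3,
                       rbc_length_um = 7.25, block_scans = 16,
                       w_min = 1e-5, n_kymo_fixtures = 3,
                       cohort_params = cohort_sim_params()) {
  stages <- match.arg(stages, c("cohort", "kymo", "oct"),
                      several.ok = TRUE)
  stopifnot(sigma_px >= 0, window_s > 0, scan_rate_hz > 0,
            min_qi %in% 1:5, rbc_length_um > 0, block_scans >= 1,
            w_min > 0, n_kymo_fixtures >= 1,
            inherits(cohort_params, "cohort_sim_params"))
  cohort_params$seed <- seed
  structure(list(seed = seed, stages = stages, out_dir = out_dir,
                 sigma_px = sigma_px, window_s = window_s,
                 scan_rate_hz = scan_rate_hz, min_qi = min_qi,
                 rbc_length_um = rbc_length_um, block_scans = block_scans,
                 w_min = w_min, n_kymo_fixtures = n_kymo_fixtures,
                 cohort_params = cohort_params,
                 version = as.character(utils::packageVersion("capillux"))),
            class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  cfg <- config
  cfg$out_dir <- NULL   # hash the analysis, not the destination
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' Run the full synthetic pipeline
#'
#' Simulates the requested inputs, runs every analysis stage on them, and
#' writes machine-readable results plus a summary mirroring the study's
#' headline tables (group means +/- SD, stall rates, regressions, group
#' comparisons). Every JSON output embeds the config hash; rerunning with
#' an identical config reproduces the outputs byte for byte.
#'
#' @param config a [run_config()].
#' @return The output directory, invisibly; `summary.json` inside it
#'   holds the headline numbers.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  summary <- list(config_hash = hash, version = config$version,
                  seed = config$seed)

  if ("cohort" %in% config$stages) {
    cohort <- simulate_cohort(config$cohort_params)
    write_cohort(cohort, file.path(config$out_dir, "cohort"))
    caps <- filter_by_quality(cohort$capillaries, config$min_qi)
    eu <- caps$group == "euglycemic"
    th <- cohort$thickness
    th_eu <- th$thickness_um[th$group == "euglycemic"]
    th_hy <- th$thickness_um[th$group == "hyperglycemic"]
    glu <- stats::aggregate(glucose_mgdl ~ group, cohort$mice, mean)
    fd_eu <- regression_r2_slope(caps$diameter_um[eu & !caps$stalled],
                                 caps$flux_cells_s[eu & !caps$stalled])
    cmp_th <- group_compare(th_hy, th_eu)
    cmp_fx <- group_compare(caps$flux_cells_s[!eu], caps$flux_cells_s[eu])
    summary$cohort <- list(
      n_capillary_obs = nrow(cohort$capillaries),
      n_retained_qi = nrow(caps),
      retention_pct = 100 * nrow(caps) / nrow(cohort$capillaries),
      glucose_mean_mgdl = stats::setNames(as.list(glu$glucose_mgdl),
                                          glu$group),
      flux_mean_eu = mean(caps$flux_cells_s[eu]),
      flux_mean_hy = mean(caps$flux_cells_s[!eu]),
      flux_skew_eu = adjusted_skew(caps$flux_cells_s[eu]),
      flux_p = cmp_fx$p,
      stall_rate_eu_pct = as.numeric(stall_rate(caps$stalled[eu])),
      stall_rate_hy_pct = as.numeric(stall_rate(caps$stalled[!eu])),
      flux_diam_slope_eu = fd_eu$slope,
      flux_diam_r2_eu = fd_eu$r_squared,
      thickness_mean_eu = mean(th_eu),
      thickness_mean_hy = mean(th_hy),
      thickness_p = cmp_th$p)
    ws <- weekly_summary(cohort, "flux_cells_s")
    utils::write.csv(ws, file.path(config$out_dir, "flux_weekly.csv"),
                     row.names = FALSE)
  }

  if ("kymo" %in% config$stages) {
    flux_rows <- lapply(seq_len(config$n_kymo_fixtures), function(i) {
      p <- kymo_sim_params(duration_s = 1,
                           scan_rate_hz = config$scan_rate_hz,
                           mean_flux_cells_s = c(25, 100, 200)[
                             1 + (i - 1) %% 3],
                           seed = config$seed * 1000 + i)
      sim <- simulate_kymograph(p)
      write_kymograph(sim$kymo,
                      file.path(config$out_dir,
                                sprintf("kymo_%02d.tiff", i)))
      write_markers(sim$markers,
                    file.path(config$out_dir,
                              sprintf("kymo_%02d_markers.csv", i)))
      fps <- flux_per_second(sim$markers, p$scan_rate_hz,
                             n_scans = ncol(sim$kymo$image),
                             window_s = config$window_s)
      det <- detect_cells_synthetic(sim$kymo)
      data.frame(fixture = i, nominal_flux = p$mean_flux_cells_s,
                 truth_flux = nrow(sim$markers) / p$duration_s,
                 marker_flux = mean(fps),
                 detected_flux = nrow(det) / p$duration_s,
                 stalled = detect_stall(sim$markers))
    })
    flux_tab <- do.call(rbind, flux_rows)
    utils::write.csv(flux_tab, file.path(config$out_dir,
                                         "kymo_flux.csv"),
                     row.names = FALSE)
    summary$kymo <- list(
      n_fixtures = nrow(flux_tab),
      median_marker_rel_err = stats::median(
        abs(flux_tab$marker_flux - flux_tab$truth_flux) /
          flux_tab$truth_flux),
      median_detect_rel_err = stats::median(
        abs(flux_tab$detected_flux - flux_tab$truth_flux) /
          flux_tab$truth_flux))
  }

  if ("oct" %in% config$stages) {
    op <- oct_sim_params(seed = config$seed * 7 + 3)
    cube <- simulate_bscan_cube(op, n_bscans = 4)
    write_bscan_cube(lapply(cube, `[[`, "bscan"),
                     file.path(config$out_dir, "oct_cube.tiff"))
    segs <- lapply(cube, function(x) segment_bscan(x$bscan, config$w_min))
    ct <- cube_thickness(segs, op$axial_pitch_um)
    err <- mapply(function(s, x) mean(abs(s$ilm_row - x$ilm_true)),
                  segs, cube)
    utils::write.csv(data.frame(bscan = seq_along(segs),
                                mean_thickness_um =
                                  rowMeans(ct$en_face_um)),
                     file.path(config$out_dir, "oct_thickness.csv"),
                     row.names = FALSE)
    summary$oct <- list(cube_mean_um = ct$cube_mean_um,
                        true_mean_um = mean(vapply(cube, function(x)
                          mean(x$thickness_true_um), 1)),
                        ilm_mae_px = mean(err))
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
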