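#' Simulate RBC arrival times at the imaging line
#'
#' Arrivals follow an inhomogeneous Poisson process with cardiac-modulated
#' rate `lambda(t) = mean_flux * (1 + depth * sin(2 pi f_cardiac t))`,
#' sampled by thinning. The process models the pulsatile but nonperiodic
#' cell traffic of a single-file capillary; modulation depth below 1 keeps
#' the rate nonnegative everywhere.
#'
#' With `process = "poisson"` (default) arrivals are a random draw from
#' the process. `process = "warped_regular"` instead passes a regular
#' train through the inverse cumulative rate, giving a deterministic
#' pulsatile train whose gaps track `1/lambda(t)`; use it where the
#' heavy-tailed gaps of a Poisson draw are unphysical (single-file flow
#' is queued, not memoryless) or where a noise-free pulsatile fixture is
#' wanted.
#'
#' @param params a [kymo_sim_params()] object.
#' @param process `"poisson"` or `"warped_regular"` (see Details).
#' @return Sorted numeric vector of arrival scan indices (0-based,
#'   fractional) in `[0, duration_s * scan_rate_hz)`. Empty when the mean
#'   flux is zero or the capillary is stalled.
#' @export
simulate_arrival_times <- function(params,
                                   process = c("poisson",
                                               "warped_regular")) {
  stopifnot(inherits(params, "kymo_sim_params"))
  process <- match.arg(process)
  n_scans <- round(params$duration_s * params$scan_rate_hz)
  if (params$stall || params$mean_flux_cells_s == 0) return(numeric())
  if (process == "warped_regular") {
    # cumulative rate Lambda(t); arrivals at its uniform quantiles
    f <- params$mean_flux_cells_s; d <- params$cardiac_mod_depth
    fc <- params$cardiac_freq_hz
    Lam <- function(t) {
      if (d == 0 || fc == 0) f * t
      else f * (t - d / (2 * pi * fc) * (cos(2 * pi * fc * t) - 1))
    }
    n <- round(f * params$duration_s)
    if (n == 0) return(numeric())
    tg <- seq(0, params$duration_s, length.out = 20000)
    t_arr <- stats::approx(Lam(tg), tg,
                           xout = (seq_len(n) - 0.5) / n *
                             Lam(params$duration_s))$y
    return(pmin(t_arr * params$scan_rate_hz, n_scans - 1e-9))
  }
  with_seed_if(params$seed, {
    lam_max <- params$mean_flux_cells_s * (1 + params$cardiac_mod_depth)
    n_cand <- stats::rpois(1, lam_max * params$duration_s)
    if (n_cand == 0) return(numeric())
    t_cand <- sort(stats::runif(n_cand, 0, params$duration_s))
    lam <- params$mean_flux_cells_s *
      (1 + params$cardiac_mod_depth *
         sin(2 * pi * params$cardiac_freq_hz * t_cand))
    keep <- stats::runif(n_cand) < lam / lam_max
    pmin(t_cand[keep] * params$scan_rate_hz, n_scans - 1e-9)
  })
}

#' Lateral eye displacement at each scan
#'
#' @param em an [eye_motion_params()] object.
#' @param n_scans number of scans.
#' @param scan_rate_hz line rate, Hz.
#' @return Numeric vector of per-scan lateral displacement in um.
#' @export
eye_motion_displacement <- function(em, n_scans, scan_rate_hz) {
  stopifnot(inherits(em, "eye_motion_params"), n_scans >= 1)
  t <- (seq_len(n_scans) - 1) / scan_rate_hz
  em$amplitude_um * sin(2 * pi * em$freq_hz * t + em$phase_rad) +
    em$drift_um_s * t
}

# Dwell of one cell in scans: time to traverse its own length at the
# given speed, sampled at the scan rate.
dwell_scans_for <- function(params) {
  max(1L, as.integer(round(
    params$rbc_length_um / params$rbc_speed_um_s * params$scan_rate_hz)))
}

#' Render a kymograph from arrival times
#'
#' Each cell is drawn as a dark blob on a bright vessel band: horizontal
#' extent equal to its dwell (`round(rbc_length / speed * scan_rate)`
#' scans), vertical extent equal to the lumen diameter projected through
#' the vessel angle (`lumen / (pitch * cos(angle))` pixels). Because flow
#' is single file, cells cannot overlap: rendered centres are queued to at
#' least two dwell times apart (one plasma gap), and the ground-truth
#' markers returned are the centroids actually rendered. Eye motion shifts
#' the vessel band vertically scan by scan; Gaussian read noise is added
#' last.
#'
#' @param arrivals sorted arrival scan indices from
#'   [simulate_arrival_times()].
#' @param params a [kymo_sim_params()] object.
#' @return A list with elements `kymo` (a [kymograph()]) and `markers`
#'   (a [cell_marker_set()] of rendered ground-truth centroids; empty for
#'   a stalled vessel).
#' @export
render_kymograph <- function(arrivals, params) {
  stopifnot(inherits(params, "kymo_sim_params"))
  if (is.unsorted(arrivals)) stop("arrivals must be sorted")
  n_scans <- round(params$duration_s * params$scan_rate_hz)
  n_px <- params$n_space_px
  theta <- params$vessel_angle_deg * pi / 180
  ext_px <- params$lumen_diameter_um / (params$pixel_pitch_um * cos(theta))
  if (ext_px > n_px)
    stop("projected vessel band (", round(ext_px, 1),
         " px) exceeds the image height (", n_px, " px)")
  dwell <- dwell_scans_for(params)

  bg <- 180
  depth <- 120
  band_depth <- 35   # faint static darkening marking the vessel band
  img <- matrix(bg, nrow = n_px, ncol = n_scans)

  disp_um <- eye_motion_displacement(params$eye_motion, n_scans,
                                     params$scan_rate_hz)
  centre_row <- n_px / 2 + disp_um / params$pixel_pitch_um

  # vessel band: supergaussian vertical profile, half-depth width = ext_px
  a_y <- (ext_px / 2) / log(2)^(1 / 6)
  rows <- seq_len(n_px)
  prof_y <- exp(-(outer(rows, centre_row, "-") / a_y)^6)  # n_px x n_scans
  img <- img - band_depth * prof_y

  markers <- numeric(0)
  if (params$stall) {
    # static stuck cell: one dark blob spanning the whole recording
    img <- img - (depth - band_depth) * prof_y
  } else if (length(arrivals) > 0) {
    # single-file queueing: centres at least 2*dwell apart
    min_gap <- 2 * dwell
    c_scan <- arrivals
    for (i in seq_along(c_scan)[-1])
      c_scan[i] <- max(c_scan[i], c_scan[i - 1] + min_gap)
    c_scan <- c_scan[c_scan + dwell / 2 <= n_scans - 1]
    a_t <- (dwell / 2) / log(2)^(1 / 4)
    half_t <- ceiling(2 * a_t)
    for (cc in c_scan) {
      j0 <- max(1L, floor(cc + 1 - half_t))
      j1 <- min(n_scans, ceiling(cc + 1 + half_t))
      jj <- j0:j1
      f_t <- exp(-(((jj - 1) - cc) / a_t)^4)
      img[, jj] <- img[, jj] -
        depth * prof_y[, jj, drop = FALSE] * rep(f_t, each = n_px)
    }
    markers <- c_scan
  }

  if (params$noise_sd > 0) {
    noise_seed <- if (is.null(params$seed)) NULL else params$seed + 1L
    img <- img + with_seed_if(noise_seed,
      matrix(stats::rnorm(length(img), 0, params$noise_sd),
             nrow = n_px))
  }

  fov <- n_px * params$pixel_pitch_um / 34  # nominal 34 um/deg mouse eye
  kymo <- kymograph(img, params$scan_rate_hz, params$pixel_pitch_um,
                    fov_deg = fov)
  mset <- if (length(markers))
    cell_marker_set(scan_index = markers,
                    space_px = stats::approx(seq_len(n_scans) - 1,
                                             centre_row, xout = markers,
                                             rule = 2)$y)
  else cell_marker_set()
  list(kymo = kymo, markers = mset)
}

#' Simulate a complete kymograph recording
#'
#' Convenience wrapper: draws arrivals and renders the image in one call.
#'
#' @inheritParams simulate_arrival_times
#' @return As [render_kymograph()], plus element `arrivals`.
#' @export
simulate_kymograph <- function(params) {
  arr <- simulate_arrival_times(params)
  out <- render_kymograph(arr, params)
  out$arrivals <- arr
  out
}
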