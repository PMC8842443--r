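#' Smooth a kymograph with a spatiotemporal Gaussian filter
#'
#' Applies an isotropic Gaussian in the (space, scan) plane; the study's
#' counting preprocessing uses sigma = 7.5 pixels to improve cell contrast
#' before marking. Metadata are unchanged.
#'
#' @param kymo a [kymograph()].
#' @param sigma_px Gaussian sigma in pixels (>= 0; 0 returns the image
#'   unchanged).
#' @return A smoothed [kymograph()].
#' @export
preprocess_kymograph <- function(kymo, sigma_px = 7.5) {
  stopifnot(inherits(kymo, "kymograph"), sigma_px >= 0)
  if (sigma_px == 0) return(kymo)
  sm <- EBImage::gblur(kymo$image, sigma = sigma_px,
                       boundary = "replicate")
  kymograph(as.matrix(sm), kymo$scan_rate_hz, kymo$pixel_pitch_um,
            kymo$fov_deg, kymo$t0_scan)
}

#' Blood cell flux per second
#'
#' Tiles the recording into contiguous half-open windows of `window_s`
#' seconds starting at `t0_scan` and reports marker count / window
#' duration for each; a marker on a window edge belongs to the later
#' window.
#'
#' @param markers a [cell_marker_set()].
#' @param scan_rate_hz line rate, scans/s.
#' @param n_scans length of the recording in scans; defaults to the
#'   smallest whole number of windows containing all markers.
#' @param window_s window length, seconds (> 0).
#' @param t0_scan scan index where the first window starts.
#' @return Numeric vector of flux values (cells/s), one per window; empty
#'   for an empty recording.
#' @export
flux_per_second <- function(markers, scan_rate_hz, n_scans = NULL,
                            window_s = 1, t0_scan = 0) {
  stopifnot(window_s > 0, scan_rate_hz > 0)
  w_scans <- window_s * scan_rate_hz
  if (is.null(n_scans)) {
    if (nrow(markers) == 0) return(numeric())
    n_scans <- ceiling((max(markers$scan_index) + 1 - t0_scan) / w_scans) *
      w_scans + t0_scan
  }
  n_win <- floor((n_scans - t0_scan) / w_scans)
  if (n_win < 1) return(numeric())
  edges <- t0_scan + w_scans * (0:n_win)
  s <- markers$scan_index[markers$scan_index >= edges[1] &
                            markers$scan_index < edges[n_win + 1]]
  if (length(s) == 0) return(rep(0, n_win))
  counts <- graphics::hist(s, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  counts / window_s
}

#' Instantaneous flux between consecutive cell markers
#'
#' For every consecutive marker pair, instantaneous flux is
#' `scan_rate / (number of scans between the markers)`, placed at the pair
#' midpoint (kept fractional).
#'
#' @param markers a [cell_marker_set()] with at least 2 markers.
#' @param scan_rate_hz line rate, scans/s.
#' @return A data frame with columns `midpoint_scan` and `flux_cells_s`
#'   of length `n_markers - 1`.
#' @export
instantaneous_flux <- function(markers, scan_rate_hz) {
  if (nrow(markers) < 2)
    stop("instantaneous flux needs at least 2 markers")
  s <- markers$scan_index
  gaps <- diff(s)
  if (any(gaps == 0)) {
    i <- which(gaps == 0)[1]
    stop(sprintf("coincident markers at scan %g (pair %d-%d): zero dwell",
                 s[i], i, i + 1L))
  }
  data.frame(midpoint_scan = (s[-length(s)] + s[-1]) / 2,
             flux_cells_s = scan_rate_hz / gaps)
}

#' Cumulative mean and SD of an instantaneous flux trace
#'
#' Element `k` summarises the first `k` instantaneous values; the SD of a
#' single value is 0 (sample SD thereafter).
#'
#' @param inst_flux numeric vector of instantaneous flux values, or the
#'   data frame returned by [instantaneous_flux()].
#' @return A data frame with columns `cumulative_mean` and
#'   `cumulative_sd`.
#' @export
cumulative_flux_stats <- function(inst_flux) {
  x <- if (is.data.frame(inst_flux)) inst_flux$flux_cells_s else inst_flux
  if (length(x) < 1) stop("need at least one instantaneous flux value")
  k <- seq_along(x)
  cmean <- cumsum(x) / k
  css <- cumsum(x^2)
  cvar <- ifelse(k > 1, pmax(0, (css - k * cmean^2) / (k - 1)), 0)
  data.frame(cumulative_mean = cmean, cumulative_sd = sqrt(cvar))
}

#' RBC instantaneous velocity from dwell time
#'
#' `V = rbc_length / dwell_time`, with dwell time the number of scans a
#' cell occupies the imaging line divided by the scan rate. The RBC length
#' is fixed at 7.25 um (compressed-cell constraint).
#'
#' @param dwell_scans integer vector of dwell lengths in scans (>= 1).
#' @param scan_rate_hz line rate, scans/s.
#' @param rbc_length_um compressed RBC length, um.
#' @return Velocity in um/s (vectorised over `dwell_scans`).
#' @export
cell_velocity <- function(dwell_scans, scan_rate_hz, rbc_length_um = 7.25) {
  if (any(dwell_scans < 1)) stop("dwell_scans must be >= 1")
  stopifnot(scan_rate_hz > 0, rbc_length_um > 0)
  rbc_length_um / (dwell_scans / scan_rate_hz)
}

#' Detect a stalled capillary
#'
#' A capillary is stalled over the analysis window iff no cell passes
#' (zero flux).
#'
#' @param markers a [cell_marker_set()].
#' @param window_scans optional `c(start, end)` half-open scan window;
#'   default considers the whole marker set.
#' @return Logical.
#' @export
detect_stall <- function(markers, window_scans = NULL) {
  s <- markers$scan_index
  if (!is.null(window_scans))
    s <- s[s >= window_scans[1] & s < window_scans[2]]
  length(s) == 0
}

#' Filter records by capillary quality index
#'
#' Keeps records whose subjective quality index (1-5) meets the analysis
#' threshold; the study counted capillaries graded 3 and above.
#'
#' @param records a data frame with a `quality_index` column.
#' @param min_qi minimum quality index retained.
#' @return The surviving rows, order preserved.
#' @export
filter_by_quality <- function(records, min_qi = 3) {
  if (!"quality_index" %in% names(records))
    stop("records must carry a quality_index column")
  if (anyNA(records$quality_index))
    stop("quality_index contains missing values")
  records[records$quality_index >= min_qi, , drop = FALSE]
}

#' Automated cell detection on simulated kymographs
#'
#' A stand-in for manual marking, intended only for simulator fixtures
#' (dark blobs on a bright background): smooth lightly, invert, remove
#' the time-static component (per-row median across scans, which carries
#' the vessel band and any stalled cell), Otsu threshold, label connected
#' components, and return one marker per component centroid. It makes no
#' claim of matching human grading on real data.
#'
#' @param kymo a [kymograph()] from the simulator family.
#' @param sigma_px detection smoothing sigma, pixels (smaller than the
#'   7.5 px counting filter so adjacent cells stay separable).
#' @param min_area_px minimum component area retained, pixels.
#' @return A [cell_marker_set()] with `grader_id = "auto"`; may be empty.
#' @export
detect_cells_synthetic <- function(kymo, sigma_px = 2, min_area_px = 4) {
  stopifnot(inherits(kymo, "kymograph"))
  sm <- preprocess_kymograph(kymo, sigma_px)$image
  inv <- max(sm) - sm
  inv <- inv - apply(inv, 1, stats::median)   # drop band + stalled cells
  noise <- stats::mad(inv)                    # robust read-noise level
  inv[inv < 0] <- 0
  rng <- range(inv)
  if (diff(rng) < .Machine$double.eps)
    return(cell_marker_set(grader_id = "auto"))
  inv01 <- (inv - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(inv01), range = c(0, 1))
  # a threshold within the noise floor means there is nothing to detect
  if (rng[1] + thr * diff(rng) < 6 * noise + .Machine$double.eps)
    return(cell_marker_set(grader_id = "auto"))
  lab <- EBImage::bwlabel(inv01 > thr)
  lab <- as.matrix(EBImage::imageData(lab))
  if (max(lab) == 0) return(cell_marker_set(grader_id = "auto"))
  idx <- which(lab > 0)
  comp <- lab[idx]
  rr <- (idx - 1) %% nrow(lab) + 1
  cc <- (idx - 1) %/% nrow(lab) + 1
  area <- tabulate(comp)
  keep <- which(area >= min_area_px)
  if (length(keep) == 0) return(cell_marker_set(grader_id = "auto"))
  r_cent <- vapply(keep, function(k) mean(rr[comp == k]), 1)
  c_cent <- vapply(keep, function(k) mean(cc[comp == k]), 1)
  cell_marker_set(scan_index = c_cent - 1, space_px = r_cent,
                  grader_id = "auto")
}
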