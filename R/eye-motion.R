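#' Register a line-scan recording along its spatial axis
#'
#' Estimates lateral retinal displacement confined to the line-scan
#' (spatial) axis: consecutive blocks of `block_scans` columns are
#' averaged into one spatial profile each, and every block profile is
#' registered to the first block by maximising the 1-D normalised
#' cross-correlation over integer lags with parabolic sub-pixel
#' refinement. Positive shift means the image content moved toward larger
#' row indices.
#'
#' @param kymo a [kymograph()] with at least 2 blocks.
#' @param block_scans scans averaged per block.
#' @param max_shift_px largest |lag| searched; defaults to a quarter of
#'   the image height.
#' @param per_scan if `TRUE`, also return the per-scan linear
#'   interpolation of the per-block shifts.
#' @return A data frame with columns `block`, `mid_scan` (0-based scan
#'   index of the block centre) and `shift_px`; attribute `flat` flags
#'   blocks with zero-variance profiles (shift reported as 0, with a
#'   warning). With `per_scan = TRUE`, attribute `per_scan` holds a data
#'   frame `scan_index, shift_px`.
#' @export
register_linescan <- function(kymo, block_scans = 16, max_shift_px = NULL,
                              per_scan = FALSE) {
  stopifnot(inherits(kymo, "kymograph"), block_scans >= 1)
  img <- kymo$image
  n_blocks <- floor(ncol(img) / block_scans)
  if (n_blocks < 2) stop("recording must contain at least 2 blocks")
  if (is.null(max_shift_px)) max_shift_px <- max(1L, nrow(img) %/% 4)

  prof <- vapply(seq_len(n_blocks), function(b) {
    rowMeans(img[, ((b - 1) * block_scans + 1):(b * block_scans),
                 drop = FALSE])
  }, numeric(nrow(img)))
  ref <- prof[, 1]
  flat <- logical(n_blocks)
  shifts <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    if (stats::sd(prof[, b]) == 0 || stats::sd(ref) == 0) {
      flat[b] <- TRUE
      next
    }
    shifts[b] <- ncc_shift(ref, prof[, b], max_shift_px)
  }
  if (any(flat))
    warning("flat (zero-variance) block profile; shift reported as 0 for ",
            sum(flat), " block(s)")
  out <- data.frame(block = seq_len(n_blocks),
                    mid_scan = (seq_len(n_blocks) - 0.5) * block_scans - 0.5,
                    shift_px = shifts)
  attr(out, "flat") <- flat
  if (per_scan) {
    sc <- 0:(ncol(img) - 1)
    attr(out, "per_scan") <- data.frame(
      scan_index = sc,
      shift_px = stats::approx(out$mid_scan, out$shift_px, xout = sc,
                               rule = 2)$y)
  }
  out
}

# 1-D shift of `cur` relative to `ref` (cur(y) ~ ref(y - s)) by
# normalised cross-correlation over integer lags, refined by fitting a
# parabola through the correlation peak and its two neighbours.
ncc_shift <- function(ref, cur, max_shift) {
  n <- length(ref)
  lags <- -max_shift:max_shift
  cc <- vapply(lags, function(L) {
    if (L >= 0) { a <- ref[1:(n - L)]; b <- cur[(1 + L):n] }
    else        { a <- ref[(1 - L):n]; b <- cur[1:(n + L)] }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }, 1)
  i <- which.max(cc)
  s <- lags[i]
  if (i > 1 && i < length(lags) && is.finite(cc[i - 1]) &&
      is.finite(cc[i + 1])) {
    denom <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (denom < 0) s <- s + 0.5 * (cc[i - 1] - cc[i + 1]) / denom
  }
  s
}

#' Eye velocity from a displacement series
#'
#' Velocity is the per-sample incremental displacement scaled by the scan
#' rate: `v[k] = (d[k] - d[k-1]) * scan_rate`, with the first element 0.
#'
#' @param displacement_um per-scan lateral displacement, um.
#' @param scan_rate_hz sampling rate of the displacement series, Hz.
#' @return Velocity series, um/s, same length as the input.
#' @export
eye_velocity <- function(displacement_um, scan_rate_hz) {
  stopifnot(scan_rate_hz > 0)
  if (length(displacement_um) == 0) return(numeric())
  c(0, diff(displacement_um)) * scan_rate_hz
}

#' Full eye-motion trace from a kymograph
#'
#' Registers the recording, converts the per-scan shift to micrometres,
#' zeroes the mean displacement (the plotted convention), and derives the
#' velocity series.
#'
#' @inheritParams register_linescan
#' @return A data frame `scan_index, displacement_um, velocity_um_s` of
#'   class `eye_motion_trace`, with the per-block table in attribute
#'   `blocks` and `block_scans` recorded.
#' @export
eye_motion_trace <- function(kymo, block_scans = 16, max_shift_px = NULL) {
  reg <- register_linescan(kymo, block_scans, max_shift_px,
                           per_scan = TRUE)
  ps <- attr(reg, "per_scan")
  disp <- ps$shift_px * kymo$pixel_pitch_um
  disp <- disp - mean(disp)
  out <- data.frame(scan_index = ps$scan_index,
                    displacement_um = disp,
                    velocity_um_s = eye_velocity(disp, kymo$scan_rate_hz))
  attr(out, "blocks") <- reg
  attr(out, "block_scans") <- block_scans
  class(out) <- c("eye_motion_trace", "data.frame")
  out
}
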