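#' Kymograph (space-time line-scan image) container
#'
#' Rows index spatial pixels along the scanned line (row 1 = superior
#' edge), columns index successive scans; a cell passing the beam appears
#' as a dark blob spanning its dwell scans.
#'
#' @param image numeric matrix, `n_space_px x n_scans`.
#' @param scan_rate_hz line-scan rate, scans/s.
#' @param pixel_pitch_um spatial sampling, um/pixel.
#' @param fov_deg field of view of the scanned line, degrees.
#' @param t0_scan integer scan-index offset of column 1 (0-based scan
#'   clock; column `j` holds scan `t0_scan + j - 1`).
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(image, scan_rate_hz, pixel_pitch_um,
                      fov_deg = NA_real_, t0_scan = 0L) {
  stopifnot(is.matrix(image), ncol(image) >= 1, nrow(image) >= 1,
            is.numeric(image), scan_rate_hz > 0, pixel_pitch_um > 0)
  structure(list(image = image, scan_rate_hz = scan_rate_hz,
                 pixel_pitch_um = pixel_pitch_um, fov_deg = fov_deg,
                 t0_scan = as.integer(t0_scan)),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d px x %d scans @ %g Hz (%.3f s), %g um/px\n",
              nrow(x$image), ncol(x$image), x$scan_rate_hz,
              ncol(x$image) / x$scan_rate_hz, x$pixel_pitch_um))
  invisible(x)
}

#' Cell-marker set: grader-placed RBC centroids on a kymograph
#'
#' Each marker is the (scan index, spatial pixel) centroid of one red
#' blood cell passage. Markers are stored sorted by scan index. Scan
#' indices are 0-based (scan clock), spatial positions 1-based pixel rows.
#'
#' @param scan_index numeric vector of scan indices (0-based).
#' @param space_px numeric vector of spatial centroids (pixel rows).
#' @param grader_id label of the grader (or `"truth"` / `"auto"`).
#' @param quality_index subjective capillary quality 1-5.
#' @param capillary_id,mouse_id,week optional provenance labels.
#' @return A `data.frame` of class `cell_marker_set` with attributes
#'   `grader_id`, `quality_index`, `capillary_id`, `mouse_id`, `week`.
#' @export
cell_marker_set <- function(scan_index = numeric(), space_px = numeric(),
                            grader_id = "truth", quality_index = 5L,
                            capillary_id = NA, mouse_id = NA, week = NA) {
  if (length(space_px) == 1L) space_px <- rep(space_px,
                                              length(scan_index))
  stopifnot(length(scan_index) == length(space_px),
            quality_index %in% 1:5)
  if (any(scan_index < 0)) stop("scan indices must be >= 0")
  o <- order(scan_index)
  out <- data.frame(scan_index = as.numeric(scan_index)[o],
                    space_px = as.numeric(space_px)[o])
  attr(out, "grader_id") <- grader_id
  attr(out, "quality_index") <- as.integer(quality_index)
  attr(out, "capillary_id") <- capillary_id
  attr(out, "mouse_id") <- mouse_id
  attr(out, "week") <- week
  class(out) <- c("cell_marker_set", "data.frame")
  out
}

#' OCT B-scan container
#'
#' @param image numeric matrix, `n_rows` axial pixels x `n_cols` A-scans;
#'   row 1 is the vitreous side.
#' @param axial_pitch_um axial sampling, um/pixel.
#' @param column_positions optional lateral indices of the columns.
#' @return An object of class `bscan`.
#' @export
bscan <- function(image, axial_pitch_um, column_positions = NULL) {
  stopifnot(is.matrix(image), nrow(image) >= 2, ncol(image) >= 2,
            is.numeric(image), axial_pitch_um > 0)
  if (is.null(column_positions)) column_positions <- seq_len(ncol(image))
  stopifnot(length(column_positions) == ncol(image))
  structure(list(image = image, axial_pitch_um = axial_pitch_um,
                 column_positions = column_positions),
            class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan> %d axial px x %d A-scans, %g um/px axial\n",
              nrow(x$image), ncol(x$image), x$axial_pitch_um))
  invisible(x)
}
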