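#' Average of the three boxed RBC width measures
#'
#' Three independent manual width measurements per line scan are averaged
#' before pixel-pitch and angle correction.
#'
#' @param widths_px numeric vector of exactly 3 finite positive widths,
#'   pixels.
#' @return Arithmetic mean, pixels.
#' @export
mean_rbc_width <- function(widths_px) {
  if (length(widths_px) != 3)
    stop("exactly 3 width measures are averaged per line scan")
  if (!all(is.finite(widths_px)) || any(widths_px <= 0))
    stop("width measures must be finite and positive")
  mean(widths_px)
}

#' Age-corrected pixel pitch from a magnification calibration table
#'
#' The growing mouse eye magnifies the retinal image with age; the
#' calibration table maps age (weeks) to retinal scale (um per degree of
#' scan angle). Pitch is `interp(age) * fov_deg / n_px`, linearly
#' interpolated between table rows and clamped at the table ends.
#'
#' @param age_weeks postnatal age, weeks.
#' @param table data frame with columns `age_weeks` (strictly increasing)
#'   and `um_per_degree` (> 0); defaults to the package's single-row
#'   synthetic placeholder (constant 34 um/deg — supply the instrument's
#'   own calibration for real data).
#' @param fov_deg scan field of view, degrees.
#' @param n_px pixels across the field.
#' @return Pixel pitch in um/px.
#' @export
pixel_pitch_for_age <- function(age_weeks, table = default_magnification(),
                                fov_deg = 0.71, n_px = 512) {
  if (is.null(table) || nrow(table) == 0)
    stop("magnification table must be nonempty")
  stopifnot(all(c("age_weeks", "um_per_degree") %in% names(table)),
            fov_deg > 0, n_px > 0, all(table$um_per_degree > 0))
  if (is.unsorted(table$age_weeks, strictly = TRUE))
    stop("table ages must be strictly increasing")
  scale <- if (nrow(table) == 1) table$um_per_degree else
    stats::approx(table$age_weeks, table$um_per_degree, xout = age_weeks,
                  rule = 2)$y
  scale * fov_deg / n_px
}

#' Synthetic placeholder magnification calibration
#'
#' A single-row constant-scale table (34 um/deg at all ages). It stands in
#' for an instrument-specific calibration and should be replaced for real
#' data; simulated fixtures carry their own pixel pitch and never depend
#' on it.
#'
#' @return A one-row calibration data frame.
#' @export
default_magnification <- function() {
  data.frame(age_weeks = 10, um_per_degree = 34)
}

#' Vessel-angle correction of a measured RBC width
#'
#' A line scan crossing the vessel at angle theta from its perpendicular
#' sees the lumen foreshortened: `diameter = width * cos(rad(theta))`.
#'
#' @param width_um measured RBC width, um.
#' @param angle_deg vessel angle from vertical, degrees in `[0, 90)`.
#' @return Corrected lumen diameter, um.
#' @export
correct_diameter <- function(width_um, angle_deg) {
  stopifnot(all(width_um > 0))
  if (any(angle_deg < 0) || any(angle_deg >= 90))
    stop("angle_deg must lie in [0, 90): a line scan parallel to the ",
         "vessel cannot measure its lumen")
  width_um * cos(angle_deg * pi / 180)
}

#' Is the vessel a capillary?
#'
#' Capillaries are defined as vessels strictly less than 7 um in lumen
#' diameter (single-file RBC flow).
#'
#' @param diameter_um lumen diameter, um (> 0).
#' @return Logical (vectorised).
#' @export
classify_capillary <- function(diameter_um) {
  stopifnot(all(diameter_um > 0))
  diameter_um < 7
}

#' Automated boxed RBC width measurement on simulator fixtures
#'
#' Reproduces the manual protocol on synthetic kymographs: places a
#' fixed-width (15 ms) box over each of the three temporally earliest
#' non-overlapping cells and measures the full vertical extent of the
#' dark trace inside the box (max - min occupied row + 1, at half the
#' blob depth).
#'
#' @param kymo a [kymograph()].
#' @param markers the fixture's [cell_marker_set()] (used for box
#'   placement).
#' @param box_width_ms box width, milliseconds.
#' @return Numeric vector of up to 3 widths in pixels (fewer if the
#'   fixture holds fewer cells); errors on a stalled/empty fixture.
#' @export
measure_rbc_widths <- function(kymo, markers, box_width_ms = 15) {
  stopifnot(inherits(kymo, "kymograph"), box_width_ms > 0)
  if (nrow(markers) == 0)
    stop("no cells to measure: stalled capillaries yield no diameter")
  half_box <- box_width_ms / 1000 * kymo$scan_rate_hz / 2
  img <- kymo$image
  picked <- numeric(0)
  for (s in markers$scan_index) {
    if (length(picked) == 3) break
    if (length(picked) && s - picked[length(picked)] < 2 * half_box) next
    picked <- c(picked, s)
  }
  bg <- stats::median(img)
  vapply(picked, function(s) {
    j0 <- max(1L, floor(s + 1 - half_box))
    j1 <- min(ncol(img), ceiling(s + 1 + half_box))
    prof <- apply(img[, j0:j1, drop = FALSE], 1, min)
    depth <- bg - min(prof)
    occ <- which(prof < bg - depth / 2)
    if (length(occ) == 0) return(NA_real_)
    diff(range(occ)) + 1
  }, 1)
}
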