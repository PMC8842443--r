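#' Read and write kymographs as TIFF with a JSON sidecar
#'
#' The image is stored as a single-page grayscale 16-bit TIFF scaled to
#' `[0, 1]` by a factor recorded in the sidecar, which also carries the
#' acquisition metadata (`scan_rate_hz`, `pixel_pitch_um`, `fov_deg`,
#' `t0_scan`, `intensity_scale`).
#'
#' @param kymo a [kymograph()].
#' @param tiff_path,json_path output paths.
#' @return `write_kymograph()`: the paths, invisibly. `read_kymograph()`:
#'   the restored [kymograph()].
#' @export
write_kymograph <- function(kymo, tiff_path,
                            json_path = sub("\\.tiff?$", ".json",
                                            tiff_path)) {
  stopifnot(inherits(kymo, "kymograph"))
  img <- kymo$image
  lo <- min(img); hi <- max(img)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((img - lo) / scale, tiff_path, bits.per.sample = 16)
  jsonlite::write_json(list(scan_rate_hz = kymo$scan_rate_hz,
                            pixel_pitch_um = kymo$pixel_pitch_um,
                            fov_deg = kymo$fov_deg,
                            t0_scan = kymo$t0_scan,
                            intensity_offset = lo,
                            intensity_scale = scale),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff_path, json_path))
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(tiff_path,
                           json_path = sub("\\.tiff?$", ".json",
                                           tiff_path)) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  img <- tiff::readTIFF(tiff_path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  kymograph(img * meta$intensity_scale + meta$intensity_offset,
            meta$scan_rate_hz, meta$pixel_pitch_um,
            meta$fov_deg %||% NA_real_, meta$t0_scan %||% 0L)
}

#' Read and write cell markers as CSV
#'
#' Dialect: header `scan_index,space_px,grader_id`.
#'
#' @param markers a [cell_marker_set()].
#' @param path CSV path.
#' @return `write_markers()`: the path, invisibly. `read_markers()`: a
#'   [cell_marker_set()] (of the first grader in the file if several;
#'   use `grader` to pick one).
#' @export
write_markers <- function(markers, path) {
  df <- data.frame(scan_index = markers$scan_index,
                   space_px = markers$space_px,
                   grader_id = attr(markers, "grader_id") %||% "truth")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @param grader grader id to load; default first in the file.
#' @export
read_markers <- function(path, grader = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("scan_index", "space_px", "grader_id") %in% names(df)))
  if (is.null(grader)) grader <- df$grader_id[1]
  df <- df[df$grader_id == grader, , drop = FALSE]
  cell_marker_set(df$scan_index, df$space_px, grader_id = grader)
}

#' Read and write an OCT B-scan cube as multi-page TIFF + JSON
#'
#' @param bscans list of [bscan()] objects sharing geometry.
#' @param tiff_path,json_path output paths.
#' @return `write_bscan_cube()`: the paths, invisibly.
#'   `read_bscan_cube()`: a list of [bscan()]s.
#' @export
write_bscan_cube <- function(bscans, tiff_path,
                             json_path = sub("\\.tiff?$", ".json",
                                             tiff_path)) {
  stopifnot(length(bscans) >= 1,
            all(vapply(bscans, inherits, TRUE, "bscan")))
  imgs <- lapply(bscans, `[[`, "image")
  hi <- max(vapply(imgs, max, 1)); lo <- min(vapply(imgs, min, 1))
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF(lapply(imgs, function(m) (m - lo) / scale),
                  tiff_path, bits.per.sample = 16)
  jsonlite::write_json(list(axial_pitch_um = bscans[[1]]$axial_pitch_um,
                            intensity_offset = lo,
                            intensity_scale = scale,
                            n_bscans = length(bscans)),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff_path, json_path))
}

#' @rdname write_bscan_cube
#' @export
read_bscan_cube <- function(tiff_path,
                            json_path = sub("\\.tiff?$", ".json",
                                            tiff_path)) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    bscan(p * meta$intensity_scale + meta$intensity_offset,
          meta$axial_pitch_um)
  })
}

#' Write the cohort tables as CSV
#'
#' Emits `<prefix>_mice.csv` (`mouse_id,group,week,glucose_mgdl,weight_g`),
#' `<prefix>_capillaries.csv` (`mouse_id,capillary_id,week,flux_cells_s,
#' diameter_um,quality_index,stalled`) and `<prefix>_thickness.csv`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param prefix path prefix for the three files.
#' @return The paths, invisibly.
#' @export
write_cohort <- function(cohort, prefix) {
  paths <- c(mice = paste0(prefix, "_mice.csv"),
             capillaries = paste0(prefix, "_capillaries.csv"),
             thickness = paste0(prefix, "_thickness.csv"))
  utils::write.csv(cohort$mice[, c("mouse_id", "group", "week",
                                   "glucose_mgdl", "weight_g")],
                   paths["mice"], row.names = FALSE)
  utils::write.csv(cohort$capillaries[, c("mouse_id", "capillary_id",
                                          "week", "flux_cells_s",
                                          "diameter_um", "quality_index",
                                          "stalled")],
                   paths["capillaries"], row.names = FALSE)
  utils::write.csv(cohort$thickness, paths["thickness"], row.names = FALSE)
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(prefix) {
  out <- list(mice = utils::read.csv(paste0(prefix, "_mice.csv")),
              capillaries = utils::read.csv(paste0(prefix,
                                                   "_capillaries.csv")),
              thickness = utils::read.csv(paste0(prefix,
                                                 "_thickness.csv")))
  out$capillaries$group <- ifelse(grepl("^eu", out$capillaries$mouse_id),
                                  "euglycemic", "hyperglycemic")
  class(out) <- "cohort_table"
  out
}
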