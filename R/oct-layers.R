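#' Build the gradient-weighted boundary graph of a B-scan
#'
#' Treats the B-scan as a graph: every pixel is a node connected to its 8
#' neighbours, plus two virtual terminal columns so the path may start and
#' end at any row. The axial intensity difference across each adjacent
#' pixel pair (sign selected by the boundary polarity, negatives clamped)
#' is min-max normalised to `[0, 1]` per B-scan, and the edge between
#' nodes `a` and `b` weighs `2 - (g_a + g_b) + w_min`; terminal edges
#' weigh `w_min`. All weights are positive, as Dijkstra requires, and a
#' strong boundary is a low-cost corridor.
#'
#' Intensity normalisation makes the segmentation invariant to affine
#' rescaling of the image.
#'
#' @param bscan a [bscan()].
#' @param polarity `"dark_to_bright"` (vitreous-ILM, OS-RPE in this
#'   reflectivity model) or `"bright_to_dark"`.
#' @param w_min small positive constant keeping edge weights positive.
#' @param lateral_sigma_px Gaussian sigma (pixels) of lateral smoothing
#'   applied to the gradient field across A-scans before normalisation;
#'   suppresses speckle-driven local detours of the path. 0 disables.
#'   Smoothing acts only along the lateral axis, so a laterally flat
#'   boundary is recovered exactly regardless.
#' @return An object of class `boundary_graph` holding the normalised
#'   gradient field and graph parameters; `no_evidence` is `TRUE` when
#'   the image carries no gradient at all (constant image).
#' @export
build_boundary_graph <- function(bscan,
                                 polarity = c("dark_to_bright",
                                              "bright_to_dark"),
                                 w_min = 1e-5, lateral_sigma_px = 1) {
  stopifnot(inherits(bscan, "bscan"), w_min > 0, lateral_sigma_px >= 0)
  polarity <- match.arg(polarity)
  img <- bscan$image
  if (!all(is.finite(img))) stop("image must be finite")
  g <- img - img[c(1, seq_len(nrow(img) - 1)), , drop = FALSE]
  g[1, ] <- 0                       # no pair above the first row
  if (polarity == "bright_to_dark") g <- -g
  g[g < 0] <- 0
  if (lateral_sigma_px > 0 && ncol(g) >= 3) {
    half <- min((ncol(g) - 1) %/% 2, ceiling(3 * lateral_sigma_px))
    kern <- stats::dnorm(-half:half, sd = lateral_sigma_px)
    kern <- matrix(kern / sum(kern), nrow = 1)
    g <- as.matrix(EBImage::filter2(g, kern, boundary = "replicate"))
  }
  gmax <- max(g)
  no_evidence <- gmax <= .Machine$double.eps * max(1, max(abs(img)))
  if (!no_evidence) g <- g / gmax
  structure(list(g = g, n_rows = nrow(img), n_cols = ncol(img),
                 w_min = w_min, polarity = polarity,
                 no_evidence = no_evidence),
            class = "boundary_graph")
}

# Flattened node id of pixel (r, c) in an n_rows x n_cols grid.
node_id <- function(r, c, n_rows) (c - 1L) * n_rows + r

#' Segment one boundary by minimum-cost path
#'
#' Finds the minimum-total-weight path from the left virtual terminal to
#' the right one with Dijkstra's algorithm and converts it to a
#' per-column boundary: the mean row of the path nodes in each column
#' (under 8-connectivity a path may occupy more than one row per column).
#'
#' @param graph a [build_boundary_graph()] result.
#' @param row_band optional admissible rows, either `c(lo, hi)` applied to
#'   every column or a list with per-column vectors `lo` and `hi`;
#'   errors if any column is left without admissible rows.
#' @return Numeric vector of per-column boundary rows, with the total
#'   path cost in attribute `cost`.
#' @export
segment_boundary <- function(graph, row_band = NULL) {
  stopifnot(inherits(graph, "boundary_graph"))
  if (graph$no_evidence)
    stop("no boundary evidence: the image carries no intensity gradient")
  n_r <- graph$n_rows; n_c <- graph$n_cols
  lo <- rep(1L, n_c); hi <- rep(n_r, n_c)
  if (!is.null(row_band)) {
    if (is.list(row_band)) {
      lo <- pmax(1L, as.integer(rep_len(row_band$lo, n_c)))
      hi <- pmin(n_r, as.integer(rep_len(row_band$hi, n_c)))
    } else {
      lo <- rep(max(1L, as.integer(row_band[1])), n_c)
      hi <- rep(min(n_r, as.integer(row_band[2])), n_c)
    }
    if (any(lo > hi)) {
      j <- which(lo > hi)[1]
      stop("row band excludes all rows in column ", j)
    }
  }
  mask <- matrix(FALSE, n_r, n_c)
  for (j in seq_len(n_c)) mask[lo[j]:hi[j], j] <- TRUE

  g <- graph$g; w_min <- graph$w_min
  from <- integer(0); to <- integer(0); w <- numeric(0)
  offsets <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1L, 1L - dr):min(n_r, n_r - dr)
    c1 <- max(1L, 1L - dc):min(n_c, n_c - dc)
    rr <- rep(r1, times = length(c1))
    cc <- rep(c1, each = length(r1))
    ok <- mask[cbind(rr, cc)] & mask[cbind(rr + dr, cc + dc)]
    if (!any(ok)) next
    rr <- rr[ok]; cc <- cc[ok]
    a <- node_id(rr, cc, n_r)
    b <- node_id(rr + dr, cc + dc, n_r)
    from <- c(from, a); to <- c(to, b)
    w <- c(w, 2 - (g[a] + g[b]) + w_min)
  }
  src <- n_r * n_c + 1L
  snk <- n_r * n_c + 2L
  left <- node_id(lo[1]:hi[1], 1L, n_r)
  right <- node_id(lo[n_c]:hi[n_c], n_c, n_r)
  from <- c(from, rep(src, length(left)), rep(snk, length(right)))
  to <- c(to, left, right)
  w <- c(w, rep(w_min, length(left) + length(right)))

  gr <- igraph::make_graph(rbind(from, to), n = snk, directed = FALSE)
  sp <- igraph::shortest_paths(gr, from = src, to = snk, weights = w,
                               output = "epath", algorithm = "dijkstra")
  ep <- sp$epath[[1]]
  nodes <- setdiff(unique(as.integer(igraph::ends(gr, ep))), c(src, snk))
  cost <- sum(w[as.integer(ep)])
  rows <- (nodes - 1L) %% n_r + 1L
  cols <- (nodes - 1L) %/% n_r + 1L
  boundary <- as.numeric(tapply(rows, factor(cols, levels = seq_len(n_c)),
                                mean))
  if (anyNA(boundary))
    stop("internal error: shortest path skipped a column")
  attr(boundary, "cost") <- cost
  boundary
}

#' Segment the ILM and OS-RPE boundaries of a B-scan
#'
#' The vitreous-ILM boundary is segmented first (dark-to-bright polarity
#' over the full image; it is the strongest such transition), then the
#' OS-RPE boundary with the admissible rows restricted strictly below the
#' ILM path, which keeps the two paths from collapsing onto the same
#' edge.
#'
#' @param bscan a [bscan()].
#' @param w_min positive edge-weight floor, passed to
#'   [build_boundary_graph()].
#' @return An object of class `layer_segmentation`: list with per-column
#'   `ilm_row` and `rpe_row`, per-column logical `flags` (manual
#'   corrections, all `FALSE` here), and `axial_pitch_um`.
#' @export
segment_bscan <- function(bscan, w_min = 1e-5) {
  gr <- build_boundary_graph(bscan, "dark_to_bright", w_min)
  ilm <- segment_boundary(gr)
  lo <- pmin(gr$n_rows, as.integer(ceiling(ilm)) + 1L)
  if (any(lo >= gr$n_rows))
    stop("OS-RPE band is empty: ILM path reaches the image bottom")
  rpe <- segment_boundary(gr, row_band = list(lo = lo, hi = gr$n_rows))
  if (any(rpe <= ilm))
    stop("internal error: OS-RPE boundary not below the ILM")
  structure(list(ilm_row = as.numeric(ilm), rpe_row = as.numeric(rpe),
                 flags = logical(length(ilm)),
                 axial_pitch_um = bscan$axial_pitch_um),
            class = "layer_segmentation")
}

#' Total retinal thickness from a layer segmentation
#'
#' Thickness is the axial distance between the vitreous-ILM and OS-RPE
#' boundaries: `(rpe_row - ilm_row) * axial_pitch_um` per A-scan.
#'
#' @param seg a [segment_bscan()] result.
#' @param axial_pitch_um axial sampling, um/pixel; defaults to the value
#'   recorded in `seg`.
#' @return A list of class `thickness_map` with `per_column_um` and the
#'   B-scan `mean_um`.
#' @export
total_retinal_thickness <- function(seg, axial_pitch_um = seg$axial_pitch_um) {
  stopifnot(inherits(seg, "layer_segmentation"), axial_pitch_um > 0)
  per_col <- (seg$rpe_row - seg$ilm_row) * axial_pitch_um
  structure(list(per_column_um = per_col, mean_um = mean(per_col)),
            class = "thickness_map")
}

#' En-face thickness of a cube and session averaging
#'
#' A cube's thickness map stacks the per-A-scan thickness of each B-scan
#' en face; repeat cubes from one imaging session are averaged into the
#' session value.
#'
#' @param segs list of [segment_bscan()] results (one per B-scan).
#' @param axial_pitch_um axial sampling, um/pixel.
#' @return A list with `en_face_um` (B-scans x columns matrix) and
#'   `cube_mean_um`.
#' @export
cube_thickness <- function(segs, axial_pitch_um = segs[[1]]$axial_pitch_um) {
  maps <- lapply(segs, total_retinal_thickness, axial_pitch_um)
  en_face <- do.call(rbind, lapply(maps, `[[`, "per_column_um"))
  list(en_face_um = en_face, cube_mean_um = mean(en_face))
}

#' @rdname cube_thickness
#' @param cube_means_um per-cube mean thickness values from one session.
#' @return `session_thickness()`: the session mean (mean of cube means).
#' @export
session_thickness <- function(cube_means_um) {
  stopifnot(length(cube_means_um) >= 1)
  mean(cube_means_um)
}

#' Apply expert corrections to a segmentation
#'
#' Overrides the boundary rows of the named columns, flags them as
#' manually corrected, and re-validates the `ilm < rpe` invariant.
#'
#' @param seg a [segment_bscan()] result.
#' @param corrections data frame with columns `column` and one or both of
#'   `ilm_row`, `rpe_row` (`NA` leaves a boundary untouched). Empty or
#'   `NULL` returns `seg` unchanged.
#' @return The corrected `layer_segmentation`.
#' @export
review_segmentation <- function(seg, corrections = NULL) {
  stopifnot(inherits(seg, "layer_segmentation"))
  if (is.null(corrections) || nrow(corrections) == 0) return(seg)
  stopifnot("column" %in% names(corrections))
  for (i in seq_len(nrow(corrections))) {
    j <- corrections$column[i]
    if (j < 1 || j > length(seg$ilm_row))
      stop("correction column ", j, " out of range")
    if (!is.null(corrections$ilm_row) && !is.na(corrections$ilm_row[i]))
      seg$ilm_row[j] <- corrections$ilm_row[i]
    if (!is.null(corrections$rpe_row) && !is.na(corrections$rpe_row[i]))
      seg$rpe_row[j] <- corrections$rpe_row[i]
    seg$flags[j] <- TRUE
  }
  if (any(seg$ilm_row >= seg$rpe_row))
    stop("correction violates the ilm_row < rpe_row invariant")
  if (any(seg$ilm_row < 1) || any(seg$rpe_row < 1))
    stop("corrected rows out of image bounds")
  seg
}
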