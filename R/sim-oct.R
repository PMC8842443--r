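#' Simulate an OCT B-scan with known layer boundaries
#'
#' Builds a piecewise-constant axial reflectivity profile per column --
#' dark vitreous above the ILM, moderately bright retina between the ILM
#' and the OS-RPE boundary, a brighter RPE band, dark below -- and applies
#' multiplicative speckle noise. The vitreous-ILM step is the strongest
#' dark-to-bright transition, as in real OCT.
#'
#' @param params an [oct_sim_params()] object.
#' @return A list with `bscan` (a [bscan()]), `ilm_true` and `rpe_true`
#'   (per-column boundary rows: the first retinal row and the first RPE
#'   row respectively), and `thickness_true_um` (per-column
#'   `(rpe - ilm) * axial_pitch_um`).
#' @export
simulate_bscan <- function(params) {
  stopifnot(inherits(params, "oct_sim_params"))
  n_r <- params$n_rows; n_c <- params$n_cols
  lc <- params$layer_contrast
  lv_vitreous <- 0.05 * lc
  lv_retina   <- 0.55 * lc
  lv_rpe      <- 0.85 * lc
  lv_below    <- 0.08 * lc
  img <- matrix(lv_vitreous, nrow = n_r, ncol = n_c)
  for (j in seq_len(n_c)) {
    ilm <- params$ilm_profile[j]
    rpe <- params$rpe_profile[j]
    img[ilm:(rpe - 1), j] <- lv_retina
    rpe_end <- min(n_r, rpe + params$rpe_band_px - 1)
    img[rpe:rpe_end, j] <- lv_rpe
    if (rpe_end < n_r) img[(rpe_end + 1):n_r, j] <- lv_below
  }
  if (params$speckle_sd > 0) {
    img <- with_seed_if(params$seed,
      img * pmax(0, 1 + matrix(stats::rnorm(n_r * n_c, 0,
                                            params$speckle_sd),
                               nrow = n_r)))
  }
  list(bscan = bscan(img, params$axial_pitch_um),
       ilm_true = params$ilm_profile,
       rpe_true = params$rpe_profile,
       thickness_true_um = (params$rpe_profile - params$ilm_profile) *
         params$axial_pitch_um)
}

#' Simulate a cube of B-scans sharing smooth boundary surfaces
#'
#' @param params an [oct_sim_params()] template; each B-scan perturbs the
#'   template profiles by a slow sinusoidal surface.
#' @param n_bscans number of B-scans in the cube.
#' @param surface_amp_px amplitude of the smooth boundary undulation,
#'   pixels.
#' @return A list of [simulate_bscan()] results, one per B-scan.
#' @export
simulate_bscan_cube <- function(params, n_bscans = 8, surface_amp_px = 3) {
  stopifnot(inherits(params, "oct_sim_params"), n_bscans >= 1)
  lapply(seq_len(n_bscans), function(b) {
    ph <- 2 * pi * b / n_bscans
    und <- surface_amp_px *
      sin(2 * pi * seq_len(params$n_cols) / params$n_cols + ph)
    p <- params
    p$ilm_profile <- pmax(2, round(params$ilm_profile + und))
    p$rpe_profile <- pmin(params$n_rows - params$rpe_band_px,
                          round(params$rpe_profile + und))
    p$seed <- if (is.null(params$seed)) NULL else params$seed + b
    simulate_bscan(p)
  })
}
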