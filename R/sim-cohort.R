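# Truncated-normal draws by rejection; lower/upper may be infinite.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(pmin(pmax(rep(mean, n), lower), upper))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  guard <- 0L
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncation region has negligible mass")
  }
  x
}

#' Simulate the longitudinal mouse cohort
#'
#' Generates weekly blood glucose and body weight, biweekly per-capillary
#' RBC flux and lumen diameter (with stalls), and 4-weekly total retinal
#' thickness for a euglycemic and a hyperglycemic group, parameterised by
#' the published group means and SDs (see [cohort_sim_params()]).
#'
#' Structure of the draws: glucose and weight are independent weekly
#' draws at the group mean/SD, glucose censored at the meter cap (600
#' mg/dL) and, for hyperglycemic mice, truncated above the 250 mg/dL
#' cutoff so the designation holds on every consecutive pair of weeks by
#' construction. Each capillary gets a persistent lumen diameter (normal,
#' truncated to the observed population range) and a persistent mean flux
#' tied to its diameter through `flux_diam_slope`; weekly observations
#' scatter around the capillary mean with the group's week-to-week CV,
#' truncated at zero (which induces the mild positive skew seen in the
#' flux distribution). A visit finds the capillary stalled (flux 0) with
#' probability `stall_prob`. Thickness sessions are independent draws at
#' the group mean/SD, averaged over two repeat cubes.
#'
#' @param params a [cohort_sim_params()] object.
#' @return A list of class `cohort_table` with data frames `mice`
#'   (`mouse_id, group, week, glucose_mgdl, weight_g`), `capillaries`
#'   (`mouse_id, capillary_id, week, flux_cells_s, diameter_um,
#'   quality_index, stalled`), and `thickness` (`mouse_id, group, week,
#'   thickness_um`).
#' @export
simulate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  with_seed_if(params$seed, {
    groups <- c("euglycemic", "hyperglycemic")
    mice <- caps <- thick <- list()
    for (g in groups) {
      eu <- g == "euglycemic"
      gl <- if (eu) params$glucose_eu_mean_sd else params$glucose_hy_mean_sd
      wt <- if (eu) params$weight_mean_sd_eu else params$weight_mean_sd_hy
      fx <- if (eu) params$flux_mean_sd_eu else params$flux_mean_sd_hy
      dm <- if (eu) params$diam_mean_sd_eu else params$diam_mean_sd_hy
      th <- if (eu) params$thickness_mean_sd_eu else params$thickness_mean_sd_hy
      cv <- if (eu) params$week_to_week_cv_eu else params$week_to_week_cv_hy
      n_cap_g <- if (eu) params$n_capillaries_eu else params$n_capillaries_hy
      p_obs <- if (eu) params$p_session_observed_eu else params$p_session_observed_hy
      qi_p <- if (eu) params$qi_probs_eu else params$qi_probs_hy
      ids <- sprintf("%s_%02d", if (eu) "eu" else "hy",
                     seq_len(params$n_mice_per_group))

      n_w <- length(params$weeks)
      for (m in ids) {
        glu <- if (eu)
          rnorm_trunc(n_w, gl[1], gl[2], lower = 0)
        else
          rnorm_trunc(n_w, gl[1], gl[2], lower = params$glucose_cutoff)
        glu <- pmin(glu, params$glucose_cap)
        mice[[length(mice) + 1L]] <- data.frame(
          mouse_id = m, group = g, week = params$weeks,
          glucose_mgdl = glu,
          weight_g = rnorm_trunc(n_w, wt[1], wt[2], lower = 1))
        n_th <- length(params$thickness_weeks)
        session <- rowMeans(matrix(
          stats::rnorm(2 * n_th,
                       rep(rnorm_trunc(n_th, th[1], th[2], lower = 1), 2),
                       1.5), ncol = 2))
        thick[[length(thick) + 1L]] <- data.frame(
          mouse_id = m, group = g, week = params$thickness_weeks,
          thickness_um = session)
      }

      # capillaries spread as evenly as possible over the group's mice
      cap_mouse <- ids[1 + (seq_len(n_cap_g) - 1) %% length(ids)]
      d_i <- rnorm_trunc(n_cap_g, dm[1], dm[2],
                         lower = params$diam_range[1],
                         upper = params$diam_range[2])
      # capillary mean flux: gamma-distributed about a conditional mean
      # linear in lumen diameter (keeps E[flux | d] linear and the
      # population positively skewed on positive support); residual SD
      # chosen so the population SD matches the group SD after adding
      # within-capillary week-to-week scatter
      var_within <- (cv * fx[1])^2
      var_slope <- (params$flux_diam_slope * dm[2])^2
      sd_resid <- sqrt(max(25, fx[2]^2 - var_slope - var_within))
      m_i <- pmax(5, fx[1] + params$flux_diam_slope * (d_i - dm[1]))
      mu_i <- stats::rgamma(n_cap_g, shape = (m_i / sd_resid)^2,
                            rate = m_i / sd_resid^2)
      for (k in seq_len(n_cap_g)) {
        wk <- params$capillary_weeks[
          stats::runif(length(params$capillary_weeks)) < p_obs]
        if (length(wk) == 0) next
        n_o <- length(wk)
        stalled <- stats::runif(n_o) < params$stall_prob
        flux <- rnorm_trunc(n_o, mu_i[k], cv * mu_i[k], lower = 0)
        flux[stalled] <- 0
        diam <- pmin(pmax(d_i[k] + stats::rnorm(n_o, 0, 0.1),
                          params$diam_range[1]), params$diam_range[2])
        caps[[length(caps) + 1L]] <- data.frame(
          mouse_id = cap_mouse[k],
          capillary_id = sprintf("cap_%03d", k),
          week = wk, flux_cells_s = flux, diameter_um = diam,
          quality_index = sample.int(5, n_o, replace = TRUE, prob = qi_p),
          stalled = stalled)
      }
    }
    out <- list(mice = do.call(rbind, mice),
                capillaries = do.call(rbind, caps),
                thickness = do.call(rbind, thick))
    out$capillaries$group <- ifelse(grepl("^eu", out$capillaries$mouse_id),
                                    "euglycemic", "hyperglycemic")
    class(out) <- "cohort_table"
    out
  })
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(paste0("<cohort_table> %d mice, %d mouse-weeks, ",
                     "%d capillary observations, %d thickness sessions\n"),
              length(unique(x$mice$mouse_id)), nrow(x$mice),
              nrow(x$capillaries), nrow(x$thickness)))
  invisible(x)
}
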