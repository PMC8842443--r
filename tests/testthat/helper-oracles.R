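# Independent oracles used across test files.

# Edge weight of the boundary graph, from the normalised gradient field.
oracle_edge_w <- function(g, a, b, w_min) 2 - (g[a] + g[b]) + w_min

# Minimum source-to-sink path cost by dynamic programming over monotone
# paths (each column visited as one contiguous vertical run, columns
# advanced left to right). Independent of the igraph-based implementation.
oracle_path_cost <- function(g, w_min = 1e-5) {
  n_r <- nrow(g); n_c <- ncol(g)
  id <- function(r, c) (c - 1L) * n_r + r
  relax_vertical <- function(d, c) {
    for (r in 2:n_r)
      d[r] <- min(d[r], d[r - 1] +
                    oracle_edge_w(g, id(r - 1, c), id(r, c), w_min))
    for (r in (n_r - 1):1)
      d[r] <- min(d[r], d[r + 1] +
                    oracle_edge_w(g, id(r + 1, c), id(r, c), w_min))
    d
  }
  d <- relax_vertical(rep(w_min, n_r), 1L)
  if (n_c > 1) for (c in 2:n_c) {
    dn <- rep(Inf, n_r)
    for (r in seq_len(n_r)) for (dr in -1:1) {
      rp <- r + dr
      if (rp >= 1 && rp <= n_r)
        dn[r] <- min(dn[r], d[rp] +
                       oracle_edge_w(g, id(rp, c - 1), id(r, c), w_min))
    }
    d <- relax_vertical(dn, c)
  }
  min(d) + w_min
}

# Exhaustive minimum cost over ALL simple source-to-sink paths in the
# full 8-connected graph (tiny images only). Validates oracle_path_cost.
oracle_path_cost_exhaustive <- function(g, w_min = 1e-5) {
  n_r <- nrow(g); n_c <- ncol(g)
  id <- function(r, c) (c - 1L) * n_r + r
  nbrs <- function(r, c) {
    out <- list()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= n_r && cc >= 1 && cc <= n_c)
        out[[length(out) + 1]] <- c(rr, cc)
    }
    out
  }
  best <- Inf
  visited <- matrix(FALSE, n_r, n_c)
  dfs <- function(r, c, cost) {
    if (cost >= best) return()
    if (c == n_c) best <<- min(best, cost + w_min)
    visited[r, c] <<- TRUE
    for (nb in nbrs(r, c)) {
      if (!visited[nb[1], nb[2]])
        dfs(nb[1], nb[2],
            cost + oracle_edge_w(g, id(r, c), id(nb[1], nb[2]), w_min))
    }
    visited[r, c] <<- FALSE
  }
  for (r0 in seq_len(n_r)) dfs(r0, 1L, w_min)
  best
}

# Normalised gradient field exactly as the implementation defines it,
# recomputed here from first principles for oracle use.
oracle_gradient <- function(img, polarity = "dark_to_bright") {
  gg <- img - img[c(1, seq_len(nrow(img) - 1)), , drop = FALSE]
  gg[1, ] <- 0
  if (polarity == "bright_to_dark") gg <- -gg
  gg[gg < 0] <- 0
  if (max(gg) > 0) gg <- gg / max(gg)
  gg
}

# Frequency (Hz) of the strongest periodogram component of arrival times
# binned at bin_s seconds over duration_s, DC excluded.
oracle_peak_freq <- function(arrival_scans, scan_rate_hz, duration_s,
                             bin_s = 0.01, f_max = 20) {
  n_bins <- round(duration_s / bin_s)
  counts <- tabulate(floor(arrival_scans / scan_rate_hz / bin_s) + 1,
                     nbins = n_bins)
  sp <- Mod(stats::fft(counts - mean(counts)))^2
  fr <- (seq_along(sp) - 1) / duration_s
  use <- fr > 0 & fr <= f_max
  fr[use][which.max(sp[use])]
}
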