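# Brute-force oracles and shared fixtures. Oracles are deliberately written
# as explicit loops, independent of the implementation paths they check.

# nested-loop crosscorrelogram: Pearson r for every displacement of A
# relative to B over co-defined bins
bf_crosscorrelogram <- function(A, B, min_overlap = 1) {
  nrA <- nrow(A); ncA <- ncol(A); nrB <- nrow(B); ncB <- ncol(B)
  dxs <- -(nrA - 1):(nrB - 1); dys <- -(ncA - 1):(ncB - 1)
  r <- matrix(NA_real_, length(dxs), length(dys))
  for (ix in seq_along(dxs)) for (iy in seq_along(dys)) {
    va <- c(); vb <- c()
    for (i in seq_len(nrA)) for (j in seq_len(ncA)) {
      ii <- i + dxs[ix]; jj <- j + dys[iy]
      if (ii >= 1 && ii <= nrB && jj >= 1 && jj <= ncB &&
          !is.na(A[i, j]) && !is.na(B[ii, jj])) {
        va <- c(va, A[i, j]); vb <- c(vb, B[ii, jj])
      }
    }
    if (length(va) >= min_overlap && stats::sd(va) > 0 && stats::sd(vb) > 0)
      r[ix, iy] <- stats::cor(va, vb)
  }
  r
}

# explicit weighted-sum smoothing of a rate map (clipped Gaussian,
# renormalized over occupied bins, < min_occupied occupied -> NA)
bf_smooth <- function(rate, occupied, size = 5, variance = 2, min_occupied = 5) {
  K <- (size - 1) / 2
  nr <- nrow(rate); nc <- ncol(rate)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    num <- 0; den <- 0; cnt <- 0
    for (di in -K:K) for (dj in -K:K) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && occupied[ii, jj]) {
        w <- exp(-(di^2 + dj^2) / (2 * variance))
        num <- num + w * rate[ii, jj]; den <- den + w; cnt <- cnt + 1
      }
    }
    if (cnt >= min_occupied) out[i, j] <- num / den
  }
  out
}

# explicit temporal clipped-Gaussian convolution with edge renormalization
bf_temporal_smooth <- function(x, sigma_frames, K = round(2 * sigma_frames)) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (k in -K:K) {
      if (i + k >= 1 && i + k <= n) {
        w <- stats::dnorm(k, sd = sigma_frames)
        num <- num + w * x[i + k]; den <- den + w
      }
    }
    out[i] <- num / den
  }
  out
}

# random rate map with NA holes, for oracle comparisons
random_map <- function(nr, nc, seed, bin_size = 3, na_frac = 0.1) {
  set.seed(seed)
  r <- matrix(runif(nr * nc, 0, 10), nr, nc)
  r[sample(nr * nc, round(na_frac * nr * nc))] <- NA
  gridframes:::new_ratemap(r, !is.na(r), bin_size,
                           seq_len(nr) * bin_size, seq_len(nc) * bin_size)
}

# noise-free map of an ideal grid on the standard platform
ideal_grid_map <- function(scale = 60, orientation = 7, phase = c(0, 0), ...,
                           scene = scene_config("STD"),
                           extent = map_extent(137, 0, 3)) {
  ratemap_from_function(grid_truth(scale = scale, orientation = orientation,
                                   phase = phase, ...), extent, scene)
}

# memoized expensive fixtures (built once per test run)
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a 20-minute simulated grid-cell session plus its smoothed map and geometry
cached_session <- function() {
  cached("session60", {
    ses <- simulate_session(grid_truth(scale = 60, orientation = 7,
                                       phase = c(5, -3)),
                            scene_config("STD"), duration = 1200, seed = 101)
    map <- gridframes:::rate_map_pipeline(ses$traj, ses$spikes, gf_config(),
                                          map_extent(137, 0, 3))
    list(ses = ses, map = map, geom = grid_geometry(map))
  })
}
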