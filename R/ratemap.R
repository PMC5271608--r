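#' Default analysis parameters
#'
#' All thresholds of the pipeline with their standard values: 3 cm bins,
#' immobility below 3 cm/s for more than 500 ms, 50 ms minimum dwell,
#' temporal smoothing sigma 300 ms, 5x5-bin spatial Gaussian with variance
#' 2 bin^2, 100 bootstrap replicates with a 95-replicate pass requirement,
#' gridness threshold 0.1, correlation fields of >= 20 contiguous bins at
#' r > 0.1, 100-bin correlogram overlap, annulus half-width 1.2 central-field
#' radii, elliptical-index thresholds 0.05 (correction) and 0.5 (rejection),
#' 20% field-to-ellipse distance bound, 125 cm maximum scale, pairing at STD
#' correlation < 0.5 with scale-ratio classes at 1.3 and 1.9, 10 control
#' perturbations, 150 um thinning distance, and n > 7 for circular tests.
#'
#' @param ... overrides of any named default.
#' @return list of class `gf_config`.
#' @export
gf_config <- function(...) {
  cfg <- list(
    bin_size = 3, speed_thresh = 3, immobility_min_dur = 0.5,
    min_dwell = 0.05, speed_sigma = 0.3,
    smooth_size = 5, smooth_variance = 2, smooth_min_occupied = 5,
    n_bootstrap = 100, bootstrap_pass = 95,
    gridness_thresh = 0.1, field_r_thresh = 0.1, field_min_bins = 20,
    min_overlap = 100, annulus_width_factor = 1.2,
    ellipse_correct_thresh = 0.05, ellipse_reject_thresh = 0.5,
    ellipse_dist_frac = 0.2, max_scale = 125,
    pair_max_corr = 0.5, sr_breaks = c(1.3, 1.9), n_controls = 10,
    thinning_um = 150, min_circ_n = 8,
    gridness_peak_offsets = c(60, 120), gridness_trough_offsets = c(30, 90, 150),
    shift_translation = 68.5
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "gf_config")
}

#' Per-frame running speed from a smoothed trajectory
#'
#' Both position series are convolved with a clipped Gaussian mask
#' (sigma = `temporal_sigma`, clipped at +/- 2 sigma, weights renormalized
#' near the series edges); speed is the displacement between consecutive
#' smoothed frames divided by the frame interval. The speed of the last
#' frame repeats the last interval's value so the vector matches the
#' trajectory length.
#'
#' @param traj `gf_trajectory` (>= 2 samples).
#' @param temporal_sigma Gaussian sigma, s.
#' @return numeric vector of speeds, cm/s, one per frame.
#' @export
estimate_speed <- function(traj, temporal_sigma = 0.3) {
  n <- nrow(traj)
  if (n < 2) stop("need at least 2 samples to estimate speed")
  fr <- attr(traj, "frame_rate") %||% (1 / stats::median(diff(traj$t)))
  K <- max(1L, round(2 * temporal_sigma * fr))
  w <- stats::dnorm(-K:K, sd = temporal_sigma * fr)
  sx <- renorm_convolve(traj$x, w)
  sy <- renorm_convolve(traj$y, w)
  dt <- diff(traj$t)
  v <- sqrt(diff(sx)^2 + diff(sy)^2) / dt
  c(v, v[length(v)])
}

# clipped-Gaussian smoothing with edge renormalization
renorm_convolve <- function(x, w) {
  n <- length(x); K <- (length(w) - 1L) / 2L
  num <- numeric(n); den <- numeric(n)
  for (k in -K:K) {
    wk <- w[k + K + 1L]
    src <- max(1L, 1L + k):min(n, n + k)
    dst <- src - k
    num[dst] <- num[dst] + wk * x[src]
    den[dst] <- den[dst] + wk
  }
  num / den
}

#' Expunge immobility epochs from trajectory and spike train
#'
#' Epochs strictly longer than `min_dur` during which the smoothed-path speed
#' stays strictly below `v_thresh` are removed from the original, unsmoothed
#' trajectory, and spikes falling inside them are dropped.
#'
#' @param traj `gf_trajectory`.
#' @param spikes `gf_spiketrain` or NULL.
#' @param v_thresh speed threshold, cm/s.
#' @param min_dur minimum epoch duration to expunge, s (strict).
#' @param temporal_sigma passed to [estimate_speed()].
#' @return list(traj, spikes, removed) where `removed` is a 2-column matrix
#'   of removed \[start, end) intervals, s.
#' @export
filter_immobility <- function(traj, spikes = NULL, v_thresh = 3, min_dur = 0.5,
                              temporal_sigma = 0.3) {
  n <- nrow(traj)
  if (n < 2) return(list(traj = traj, spikes = spikes,
                         removed = matrix(numeric(0), ncol = 2)))
  fr <- attr(traj, "frame_rate") %||% (1 / stats::median(diff(traj$t)))
  dt <- 1 / fr
  slow <- estimate_speed(traj, temporal_sigma) < v_thresh
  r <- rle(slow)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  drop <- rep(FALSE, n)
  removed <- NULL
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    dur <- r$lengths[k] * dt
    if (dur > min_dur) {
      drop[starts[k]:ends[k]] <- TRUE
      removed <- rbind(removed, c(traj$t[starts[k]], traj$t[starts[k]] + dur))
    }
  }
  out_t <- traj[!drop, , drop = FALSE]
  attr(out_t, "frame_rate") <- fr
  class(out_t) <- class(traj)
  if (!is.null(spikes)) {
    keep <- rep(TRUE, length(spikes$times))
    if (!is.null(removed))
      for (k in seq_len(nrow(removed)))
        keep <- keep & !(spikes$times >= removed[k, 1] & spikes$times < removed[k, 2])
    spikes <- spike_train(spikes$times[keep], spikes$unit)
  }
  if (is.null(removed)) removed <- matrix(numeric(0), ncol = 2)
  list(traj = out_t, spikes = spikes, removed = removed)
}

#' Map extent for a platform session
#'
#' Bin edges are anchored to the platform's bounding box in the analysis
#' frame (a rotated platform occupies a larger axis-aligned square),
#' symmetric about the platform center and snapped to whole bins.
#'
#' @param platform_side cm.
#' @param rotation platform rotation, degrees CW (enlarges the bounding box).
#' @param bin_size cm.
#' @return list(x_edges, y_edges), cm.
#' @export
map_extent <- function(platform_side = 137, rotation = 0, bin_size = 3) {
  t <- rotation * pi / 180
  half <- platform_side / 2 * (abs(cos(t)) + abs(sin(t)))
  nb <- ceiling(2 * half / bin_size / 2) * 2      # even bin count, center on 0
  e <- seq(-nb / 2, nb / 2) * bin_size
  list(x_edges = e, y_edges = e)
}

new_ratemap <- function(rate, occupied, bin_size, x, y, frame = "analysis") {
  structure(list(rate = rate, occupied = occupied, bin_size = bin_size,
                 x = x, y = y, frame = frame), class = "gf_ratemap")
}

#' @export
print.gf_ratemap <- function(x, ...) {
  cat(sprintf("<rate map %dx%d bins (%g cm), %d occupied, peak %.2f Hz>\n",
              nrow(x$rate), ncol(x$rate), x$bin_size, sum(x$occupied),
              suppressWarnings(max(x$rate, na.rm = TRUE))))
  invisible(x)
}

#' Unsmoothed occupancy-normalized firing-rate map
#'
#' Bins the (already immobility-filtered) trajectory into square bins,
#' divides per-bin spike counts by dwell time, and marks bins with less than
#' `min_dwell` of dwell as unoccupied. Spike positions are linearly
#' interpolated on the filtered trajectory.
#'
#' @param traj filtered `gf_trajectory`.
#' @param spikes filtered `gf_spiketrain`.
#' @param bin_size cm.
#' @param min_dwell minimum dwell per occupied bin, s.
#' @param extent list(x_edges, y_edges) (see [map_extent()]); derived from
#'   the data's bounding square when NULL.
#' @return unsmoothed `gf_ratemap`.
#' @export
compute_rate_map <- function(traj, spikes, bin_size = 3, min_dwell = 0.05,
                             extent = NULL) {
  if (nrow(traj) == 0) stop("empty trajectory")
  fr <- attr(traj, "frame_rate") %||% 30
  dt <- 1 / fr
  if (is.null(extent)) {
    half <- max(abs(c(traj$x, traj$y)))
    nb <- ceiling(half / bin_size) * 2
    e <- seq(-nb / 2, nb / 2) * bin_size
    extent <- list(x_edges = e, y_edges = e)
  }
  xe <- extent$x_edges; ye <- extent$y_edges
  nx <- length(xe) - 1L; ny <- length(ye) - 1L
  bx <- pmin(pmax(findInterval(traj$x, xe, rightmost.closed = TRUE), 1L), nx)
  by <- pmin(pmax(findInterval(traj$y, ye, rightmost.closed = TRUE), 1L), ny)
  occ <- matrix(0, nx, ny)
  occ[] <- tabulate(bx + nx * (by - 1L), nbins = nx * ny) * dt
  cnt <- matrix(0, nx, ny)
  st <- spikes$times
  st <- st[st >= traj$t[1] & st <= traj$t[nrow(traj)]]
  if (length(st)) {
    sxp <- stats::approx(traj$t, traj$x, st, rule = 2)$y
    syp <- stats::approx(traj$t, traj$y, st, rule = 2)$y
    sbx <- pmin(pmax(findInterval(sxp, xe, rightmost.closed = TRUE), 1L), nx)
    sby <- pmin(pmax(findInterval(syp, ye, rightmost.closed = TRUE), 1L), ny)
    cnt[] <- tabulate(sbx + nx * (sby - 1L), nbins = nx * ny)
  }
  occupied <- occ >= min_dwell
  rate <- ifelse(occupied, cnt / occ, NA_real_)
  xc <- (xe[-1] + xe[-length(xe)]) / 2
  yc <- (ye[-1] + ye[-length(ye)]) / 2
  m <- new_ratemap(rate, occupied, bin_size, xc, yc)
  attr(m, "spike_count") <- sum(cnt[occupied])
  attr(m, "dwell") <- occ
  m
}

#' Smooth a rate map with a clipped, renormalized 2-D Gaussian
#'
#' A `size` x `size` Gaussian mask (variance in bin^2) is renormalized at
#' every step over the occupied bins it covers; an output bin is marked
#' unoccupied when fewer than `min_occupied` occupied bins fall inside the
#' mask.
#'
#' @param map unsmoothed `gf_ratemap`.
#' @param size mask side in bins (odd).
#' @param variance mask variance, bin^2.
#' @param min_occupied minimum occupied bins under the mask.
#' @return smoothed `gf_ratemap`.
#' @export
smooth_rate_map <- function(map, size = 5, variance = 2, min_occupied = 5) {
  K <- (size - 1L) / 2L
  nr <- nrow(map$rate); nc <- ncol(map$rate)
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc); cntm <- matrix(0L, nr, nc)
  r0 <- map$rate; r0[!map$occupied] <- 0
  occ <- map$occupied * 1
  for (di in -K:K) for (dj in -K:K) {
    w <- exp(-(di^2 + dj^2) / (2 * variance))
    si <- max(1L, 1L + di):min(nr, nr + di)
    sj <- max(1L, 1L + dj):min(nc, nc + dj)
    ti <- si - di; tj <- sj - dj
    num[ti, tj] <- num[ti, tj] + w * r0[si, sj]
    den[ti, tj] <- den[ti, tj] + w * occ[si, sj]
    cntm[ti, tj] <- cntm[ti, tj] + occ[si, sj]
  }
  ok <- cntm >= min_occupied
  out <- map
  out$rate <- ifelse(ok, num / pmax(den, .Machine$double.eps), NA_real_)
  out$occupied <- ok
  out
}

# one-call pipeline: filter -> bin -> smooth (shared by bootstraps etc.)
rate_map_pipeline <- function(traj, spikes, cfg = gf_config(), extent = NULL,
                              smoothed = TRUE) {
  f <- filter_immobility(traj, spikes, cfg$speed_thresh, cfg$immobility_min_dur,
                         cfg$speed_sigma)
  m <- compute_rate_map(f$traj, f$spikes, cfg$bin_size, cfg$min_dwell, extent)
  if (smoothed)
    m <- smooth_rate_map(m, cfg$smooth_size, cfg$smooth_variance,
                         cfg$smooth_min_occupied)
  m
}

#' Bootstrap rate maps by spike-train resampling
#'
#' The spike train is resampled with replacement to a train of equal size,
#' and the entire pipeline (immobility filtering, binning, smoothing) is
#' reapplied, `n` times.
#'
#' @param traj original (unfiltered) `gf_trajectory`.
#' @param spikes original `gf_spiketrain` (>= 1 spike).
#' @param n replicates.
#' @param seed integer seed.
#' @param cfg [gf_config()].
#' @param extent map extent (see [compute_rate_map()]).
#' @return list of `n` smoothed `gf_ratemap`s.
#' @export
bootstrap_rate_maps <- function(traj, spikes, n = 100, seed = 1,
                                cfg = gf_config(), extent = NULL) {
  ns <- length(spikes$times)
  if (ns < 1) stop("bootstrap requires at least one spike")
  # the immobility filter depends only on the trajectory, so it is computed
  # once; per replicate the resampled spikes are expunged from the same
  # epochs before binning and smoothing, which is identical to rerunning
  # the full pipeline
  f <- filter_immobility(traj, NULL, cfg$speed_thresh, cfg$immobility_min_dur,
                         cfg$speed_sigma)
  drop_removed <- function(times) {
    keep <- rep(TRUE, length(times))
    if (nrow(f$removed))
      for (k in seq_len(nrow(f$removed)))
        keep <- keep & !(times >= f$removed[k, 1] & times < f$removed[k, 2])
    times[keep]
  }
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      res <- spike_train(drop_removed(sample(spikes$times, ns, replace = TRUE)),
                         spikes$unit)
      m <- compute_rate_map(f$traj, res, cfg$bin_size, cfg$min_dwell, extent)
      smooth_rate_map(m, cfg$smooth_size, cfg$smooth_variance,
                      cfg$smooth_min_occupied)
    })
  })
}

#' Pearson correlation between two rate maps on common occupied bins
#' @param a,b `gf_ratemap`s on the same grid.
#' @return Pearson r (NA if < 2 common bins).
#' @export
map_correlation <- function(a, b) {
  common <- a$occupied & b$occupied
  if (sum(common) < 2) return(NA_real_)
  stats::cor(a$rate[common], b$rate[common])
}

#' Split-half stability of a session's rate map
#'
#' Smoothed rate maps are built from the first and second halves of the
#' session (split at the temporal midpoint) and correlated over bins
#' occupied in both.
#'
#' @param traj `gf_trajectory`.
#' @param spikes `gf_spiketrain`.
#' @param cfg [gf_config()].
#' @param extent map extent.
#' @param min_duration minimum session length to attempt, s (sessions no
#'   longer than this are skipped with a warning and return NA).
#' @return Pearson r, with attribute `n_bins`.
#' @export
split_half_correlation <- function(traj, spikes, cfg = gf_config(),
                                   extent = NULL, min_duration = 1800) {
  dur <- diff(range(traj$t))
  if (!(dur > min_duration)) {
    warning(sprintf("session lasts %.0f s <= %.0f s; split-half skipped", dur, min_duration))
    return(NA_real_)
  }
  mid <- (traj$t[1] + traj$t[nrow(traj)]) / 2
  split_one <- function(sel_t, sel_s) {
    tr <- traj[sel_t, , drop = FALSE]
    attr(tr, "frame_rate") <- attr(traj, "frame_rate")
    class(tr) <- class(traj)
    rate_map_pipeline(tr, spike_train(spikes$times[sel_s], spikes$unit), cfg, extent)
  }
  m1 <- split_one(traj$t < mid, spikes$times < mid)
  m2 <- split_one(traj$t >= mid, spikes$times >= mid)
  r <- map_correlation(m1, m2)
  attr(r, "n_bins") <- sum(m1$occupied & m2$occupied)
  r
}

#' Noise-free rate map evaluated from a rate function
#'
#' Evaluates an analytic rate function at bin centers over a platform
#' aperture; used for parameter-recovery and limit-case checks.
#'
#' @param rate_fn function(x, y) -> Hz, or a `gf_gridtruth`.
#' @param extent list(x_edges, y_edges).
#' @param scene optional [scene_config()]; bins outside the (possibly
#'   rotated) platform aperture are marked unoccupied.
#' @return smoothed-equivalent `gf_ratemap` (no smoothing applied).
#' @export
ratemap_from_function <- function(rate_fn, extent = map_extent(), scene = NULL) {
  if (inherits(rate_fn, "gf_gridtruth")) {
    truth <- rate_fn
    rate_fn <- function(x, y) grid_rate_function(x, y, truth)
  }
  xe <- extent$x_edges; ye <- extent$y_edges
  xc <- (xe[-1] + xe[-length(xe)]) / 2
  yc <- (ye[-1] + ye[-length(ye)]) / 2
  g <- expand.grid(x = xc, y = yc)
  rate <- matrix(rate_fn(g$x, g$y), length(xc), length(yc))
  occ <- matrix(TRUE, length(xc), length(yc))
  if (!is.null(scene)) {
    p <- rotate_cw(g$x, g$y, -scene$platform_rotation)  # back to platform frame
    half <- scene$platform_side / 2
    occ[] <- abs(p$x) <= half & abs(p$y) <= half
    rate[!occ] <- NA_real_
  }
  new_ratemap(rate, occ, bin_size = xe[2] - xe[1], x = xc, y = yc)
}

#' Image plot of a rate map
#' @param x `gf_ratemap`.
#' @param ... passed to [graphics::image()].
#' @export
plot.gf_ratemap <- function(x, ...) {
  graphics::image(x$x, x$y, x$rate, asp = 1, xlab = "x (cm)", ylab = "y (cm)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
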