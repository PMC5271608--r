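make_traj <- function(x, y, fr = 30) {
  trajectory(t = seq_along(x) / fr - 1 / fr, x = x, y = y, frame_rate = fr)
}

test_that("speed estimation matches a direct convolution oracle", {
  expect_error(estimate_speed(make_traj(1, 1)), "2 samples")
  still <- make_traj(rep(3, 200), rep(-2, 200))
  expect_equal(estimate_speed(still), rep(0, 200))
  # straight line at 10 cm/s: symmetric smoothing preserves interior speeds
  line <- make_traj((0:199) / 3, rep(0, 200))
  expect_equal(estimate_speed(line)[30:170], rep(10, 141), tolerance = 1e-9)
  # jittered path vs explicit weighted sum
  set.seed(11)
  x <- cumsum(rnorm(150)); y <- cumsum(rnorm(150))
  tr <- make_traj(x, y)
  sig_frames <- 0.3 * 30
  sx <- bf_temporal_smooth(x, sig_frames); sy <- bf_temporal_smooth(y, sig_frames)
  v <- sqrt(diff(sx)^2 + diff(sy)^2) * 30
  expect_equal(estimate_speed(tr), c(v, v[149]), tolerance = 1e-9)
})

test_that("immobility epochs are expunged by the strict 500 ms / 3 cm/s rule", {
  # near-identity temporal smoothing isolates the epoch rule itself (the
  # smoothing kernel is oracle-tested separately)
  sig <- 1e-3
  slow <- function(n) rep(0.05, n)     # 1.5 cm/s steps
  fast <- function(n) rep(0.5, n)      # 15 cm/s steps
  with_epoch <- function(n_slow) {
    steps <- c(fast(60), slow(n_slow), fast(60))
    make_traj(cumsum(steps), rep(0, length(steps)))
  }
  # 600 ms slow epoch: removed together with its spikes
  tr <- with_epoch(18)
  spk <- spike_train(c(1.0, 2.2, 3.5))   # 2.2 s falls inside the slow epoch
  out <- filter_immobility(tr, spk, temporal_sigma = sig)
  expect_equal(nrow(out$traj), nrow(tr) - 18)
  expect_equal(out$spikes$times, c(1.0, 3.5))
  # 400 ms slow epoch: retained; 500 ms exactly: retained (strict "longer
  # than"); 533 ms: removed
  expect_equal(nrow(filter_immobility(with_epoch(12), temporal_sigma = sig)$traj),
               132)
  expect_equal(nrow(filter_immobility(with_epoch(15), temporal_sigma = sig)$traj),
               135)
  expect_equal(nrow(filter_immobility(with_epoch(16), temporal_sigma = sig)$traj),
               120)
  # everything fast: untouched
  tr3 <- make_traj(cumsum(fast(100)), rep(0, 100))
  expect_equal(nrow(filter_immobility(tr3)$traj), 100)
  # at the default 300-ms smoothing, a pause-and-reverse standstill in a
  # simulated session is expunged
  sim <- simulate_trajectory(600, scene_config("STD"), seed = 3)
  fsim <- filter_immobility(sim)
  expect_gt(nrow(fsim$removed), 0)
  expect_lt(nrow(fsim$traj), nrow(sim))
})

test_that("rate maps divide spike counts by dwell with the 50 ms rule", {
  expect_error(compute_rate_map(make_traj(numeric(0), numeric(0)),
                                spike_train(numeric(0))), "empty")
  tr <- simulate_trajectory(300, scene_config("STD"), seed = 21)
  m0 <- compute_rate_map(tr, spike_train(numeric(0)),
                         extent = map_extent(137, 0, 3))
  expect_true(all(m0$rate[m0$occupied] == 0))
  # a bin with 40 ms dwell (one frame + margin) is unoccupied
  one_frame <- make_traj(c(rep(10, 50), 40, rep(10, 50)),
                         rep(10, 101))          # single visit to x = 40
  m1 <- compute_rate_map(one_frame, spike_train(numeric(0)),
                         extent = map_extent(137, 0, 3))
  bx <- findInterval(40, seq(-69, 69, 3)); by <- findInterval(10, seq(-69, 69, 3))
  expect_false(m1$occupied[bx, by])
  expect_equal(attr(m1, "dwell")[bx, by], 1 / 30, tolerance = 1e-9)
  # homogeneous Poisson at r Hz: mean occupied-bin rate within 3 S.E. of r
  r <- 6
  spk <- generate_spikes(tr, function(x, y) rep(r, length(x)), seed = 5,
                         rate_max = r)
  m2 <- compute_rate_map(tr, spk, extent = map_extent(137, 0, 3))
  dwell <- attr(m2, "dwell")[m2$occupied]
  est <- sum(m2$rate[m2$occupied] * dwell) / sum(dwell)
  se <- sqrt(r / sum(dwell))
  expect_lt(abs(est - r), 3 * se)
  # spike-count conservation: rate x dwell over occupied bins recovers every
  # spike except those landing in sub-dwell (unoccupied) bins, counted
  # independently here
  xe <- seq(-69, 69, 3)
  sx <- stats::approx(tr$t, tr$x, spk$times)$y
  sy <- stats::approx(tr$t, tr$y, spk$times)$y
  in_occ <- m2$occupied[cbind(findInterval(sx, xe, rightmost.closed = TRUE),
                              findInterval(sy, xe, rightmost.closed = TRUE))]
  expect_equal(sum(m2$rate[m2$occupied] * dwell), sum(in_occ))
  expect_equal(attr(m2, "spike_count"), sum(in_occ))
})

test_that("spatial smoothing matches the explicit double-loop oracle", {
  m <- random_map(15, 12, seed = 31)
  sm <- smooth_rate_map(m)
  oracle <- bf_smooth(ifelse(m$occupied, m$rate, 0), m$occupied)
  expect_equal(sm$rate, oracle, tolerance = 1e-9)
  # constant map with full occupancy is unchanged
  const <- gridframes:::new_ratemap(matrix(4, 10, 10), matrix(TRUE, 10, 10),
                                    3, 1:10 * 3, 1:10 * 3)
  expect_equal(smooth_rate_map(const)$rate, matrix(4, 10, 10), tolerance = 1e-12)
  # a neighborhood with only 4 occupied bins yields a missing output
  sparse_rate <- matrix(NA_real_, 11, 11)
  occ <- matrix(FALSE, 11, 11)
  occ[6, 5:7] <- TRUE; occ[7, 6] <- TRUE
  sparse_rate[occ] <- 1
  sp <- gridframes:::new_ratemap(sparse_rate, occ, 3, 1:11 * 3, 1:11 * 3)
  expect_true(is.na(smooth_rate_map(sp)$rate[6, 6]))
  # convex combination: occupied-neighborhood bounds are respected
  rng <- range(m$rate[m$occupied])
  expect_true(all(sm$rate[!is.na(sm$rate)] >= rng[1] - 1e-12 &
                    sm$rate[!is.na(sm$rate)] <= rng[2] + 1e-12))
})

test_that("bootstrap maps resample spikes with replacement, deterministically", {
  tr <- simulate_trajectory(200, scene_config("STD"), seed = 41)
  spk <- generate_spikes(tr, function(x, y) rep(5, length(x)), seed = 6,
                         rate_max = 5)
  expect_error(bootstrap_rate_maps(tr, spike_train(numeric(0)), n = 3, seed = 1),
               "one spike")
  a <- bootstrap_rate_maps(tr, spk, n = 5, seed = 9)
  b <- bootstrap_rate_maps(tr, spk, n = 5, seed = 9)
  expect_equal(a, b)
  # the resample is of equal size and the filtered map retains every spike
  # that falls in an occupied bin
  f <- filter_immobility(tr, spk)
  m_unsm <- compute_rate_map(f$traj, f$spikes, extent = map_extent(137, 0, 3))
  expect_lte(attr(m_unsm, "spike_count"), length(f$spikes$times))
  expect_gt(attr(m_unsm, "spike_count"), 0.9 * length(f$spikes$times))
  # the replicate-mean map approaches the original map as n grows
  orig <- gridframes:::rate_map_pipeline(tr, spk, gf_config(),
                                         map_extent(137, 0, 3))
  mad_of <- function(n) {
    maps <- bootstrap_rate_maps(tr, spk, n = n, seed = 13)
    avg <- Reduce(`+`, lapply(maps, function(m) ifelse(m$occupied, m$rate, 0))) / n
    common <- orig$occupied
    mean(abs(avg[common] - orig$rate[common]))
  }
  expect_lt(mad_of(60), mad_of(8))
})

test_that("split-half stability is high for stable fields, nil for noise", {
  # identical halves by construction: second half repeats the first
  tr1 <- simulate_trajectory(1000, scene_config("STD"), seed = 51)
  tr <- trajectory(c(tr1$t, tr1$t + 1000), c(tr1$x, tr1$x), c(tr1$y, tr1$y))
  spk1 <- generate_spikes(tr1, function(x, y) grid_rate_function(x, y, grid_truth()),
                          seed = 3, rate_max = 15)
  spk <- spike_train(c(spk1$times, spk1$times + 1000))
  r <- split_half_correlation(tr, spk, extent = map_extent(137, 0, 3))
  expect_equal(as.numeric(r), 1, tolerance = 1e-9)
  # too-short sessions are skipped with a warning
  expect_warning(r2 <- split_half_correlation(tr1, spk1), "skipped")
  expect_true(is.na(r2))
  # spatially untuned cell: near-zero stability over > 1000 common bins
  trn <- simulate_trajectory(2000, scene_config("STD"), seed = 52)
  spn <- generate_spikes(trn, function(x, y) rep(4, length(x)), seed = 8,
                         rate_max = 4)
  # smoothing leaves ~100 effective independent patches in ~1500 bins, so
  # single-session noise correlations scatter around 0 with s.d. ~ 0.1
  rn <- split_half_correlation(trn, spn, extent = map_extent(137, 0, 3))
  expect_gt(attr(rn, "n_bins"), 1000)
  expect_lt(abs(as.numeric(rn)), 0.25)
  # stable simulated grid over 40 minutes: strong stability
  ses <- simulate_session(grid_truth(scale = 60, orientation = 7),
                          scene_config("STD"), duration = 2400, seed = 53)
  rg <- split_half_correlation(ses$traj, ses$spikes,
                               extent = map_extent(137, 0, 3))
  expect_gt(as.numeric(rg), 0.6)
})
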