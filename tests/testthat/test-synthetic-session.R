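test_that("trajectory generator honors duration, bounds and determinism", {
  sc <- scene_config("STD")
  expect_error(simulate_trajectory(-1, sc), "non-negative")
  t0 <- simulate_trajectory(0, sc)
  expect_equal(nrow(t0), 0)
  a <- simulate_trajectory(60, sc, seed = 7)
  b <- simulate_trajectory(60, sc, seed = 7)
  expect_identical(a, b)
  expect_true(all(abs(a$x) <= 137 / 2 & abs(a$y) <= 137 / 2))
  expect_equal(nrow(a), 60 * 30)
  expect_equal(diff(a$t), rep(1 / 30, nrow(a) - 1), tolerance = 1e-12)
})

test_that("long foraging runs pause, cover the platform and dwell uniformly", {
  tr <- simulate_trajectory(1200, scene_config("STD"), seed = 5)
  sp <- estimate_speed(tr)
  runs <- rle(sp < 3)
  expect_gt(sum(runs$values & runs$lengths > 15), 5)   # pauses > 500 ms exist
  f <- filter_immobility(tr)
  m <- compute_rate_map(f$traj, spike_train(numeric(0)),
                        extent = map_extent(137, 0, 3))
  occ <- attr(m, "dwell")
  g <- expand.grid(x = m$x, y = m$y)
  on_platform <- matrix(abs(g$x) <= 67 & abs(g$y) <= 67, length(m$x))
  fully_reachable <- matrix(abs(g$x) <= 66 & abs(g$y) <= 66, length(m$x))
  expect_gte(mean(occ[on_platform] >= 0.05), 0.95)
  d <- occ[fully_reachable]
  expect_lt(stats::sd(d) / mean(d), 0.5)
})

test_that("grid rate function peaks at vertices and is lattice-periodic", {
  expect_error(grid_truth(scale = -5), "positive")
  for (model in c("cosine", "gaussian")) {
    tr <- grid_truth(scale = 50, orientation = 13, phase = c(4, -9),
                     peak_rate = 15, model = model)
    expect_equal(grid_rate_function(4, -9, tr), 15)
    a1 <- 50 * gridframes:::dir_cw(13)
    a2 <- 50 * gridframes:::dir_cw(73)
    set.seed(3)
    xs <- runif(25, -60, 60); ys <- runif(25, -60, 60)
    for (v in list(a1, a2, 2 * a1 - a2, a1 + a2)) {
      expect_equal(grid_rate_function(xs + v[1], ys + v[2], tr),
                   grid_rate_function(xs, ys, tr), tolerance = 1e-9)
    }
    expect_true(all(grid_rate_function(xs, ys, tr) >= 0))
  }
})

test_that("noise-free geometry estimates recover the configured lattice", {
  for (sc in c(50, 90)) for (ori in c(0, 23)) {
    g <- grid_geometry(ideal_grid_map(scale = sc, orientation = ori))
    expect_true(g$ok)
    expect_lt(abs(wrap_grid_angle(g$orientation - ori)), 2)
    expect_lt(abs(g$scale - sc) / sc, 0.05)
  }
})

test_that("Poisson thinning matches its bound and a discretized oracle", {
  sc <- scene_config("STD")
  tr <- simulate_trajectory(10, sc, seed = 1)
  none <- generate_spikes(tr, function(x, y) rep(0, length(x)), seed = 2,
                          rate_max = 5)
  expect_length(none$times, 0)
  expect_error(generate_spikes(tr, function(x, y) rep(10, length(x)), seed = 2,
                               rate_max = 5), "exceeds")
  expect_error(generate_spikes(tr, function(x, y) rep(1, length(x)), seed = 2,
                               rate_max = Inf), "finite")

  # constant rate r over duration T: counts concentrate around r*T
  trl <- simulate_trajectory(100, sc, seed = 4)
  r <- 8
  counts <- vapply(1:20, function(s)
    length(generate_spikes(trl, function(x, y) rep(r, length(x)), seed = s,
                           rate_max = r)$times), 0)
  expect_true(all(abs(counts - r * 100) < 4 * sqrt(r * 100)))
  st <- generate_spikes(trl, function(x, y) rep(r, length(x)), seed = 1,
                        rate_max = r)
  expect_true(all(st$times >= trl$t[1] & st$times <= trl$t[nrow(trl)]))

  # thinning vs brute-force 1-ms Bernoulli oracle on a 10-s toy trajectory
  rate_fn <- function(x, y) 10 * (x > 0)   # inhomogeneous half-platform rate
  thin_counts <- vapply(1:300, function(s)
    length(generate_spikes(tr, rate_fn, seed = s, rate_max = 10)$times), 0)
  oracle_counts <- vapply(1:300, function(s) {
    set.seed(s + 9000)
    tg <- seq(tr$t[1], tr$t[nrow(tr)], by = 1e-3)
    xg <- stats::approx(tr$t, tr$x, tg)$y
    yg <- stats::approx(tr$t, tr$y, tg)$y
    sum(stats::runif(length(tg)) < rate_fn(xg, yg) * 1e-3)
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(thin_counts, oracle_counts))$p.value,
            0.01)
})

test_that("anchoring policies transform ground truth as configured", {
  std <- scene_config("STD")
  expect_error(apply_manipulation(grid_truth(), scene_config("ROT20"),
                                  scene_config("ROT70")), "STD")
  # room anchoring: unchanged under rotation; translated aperture in SHIFT
  room <- grid_truth(scale = 60, orientation = 7, phase = c(5, -3),
                     anchoring = "room")
  r70 <- apply_manipulation(room, std, scene_config("ROT70"))
  expect_equal(r70$orientation, 7)
  expect_equal(r70$phase, c(5, -3))
  rsh <- apply_manipulation(room, std, scene_config("SHIFT"))
  expect_equal(rsh$phase, c(5 - 68.5, -3))
  # platform anchoring with 6-degree undershoot: +14 in the room for ROT20
  plat <- grid_truth(scale = 60, orientation = 7, anchoring = "platform",
                     under_rotation = 6)
  p20 <- apply_manipulation(plat, std, scene_config("ROT20"))
  expect_equal(wrap_grid_angle(p20$orientation - plat$orientation), 14)
  # geometry anchoring: ROT70 follows the congruent -20 (20 CCW)
  geo <- grid_truth(scale = 60, orientation = 7, anchoring = "geometry")
  g70 <- apply_manipulation(geo, std, scene_config("ROT70"))
  expect_equal(wrap_grid_angle(g70$orientation - geo$orientation), -20)
  # STD "manipulation" leaves every policy untouched
  for (tr in list(room, plat, geo))
    expect_equal(apply_manipulation(tr, std, std)$orientation, tr$orientation)
})

test_that("boundary cells hug their wall through platform rotations", {
  expect_error(boundary_rate_function(0, 0, "N", width = -1), "positive")
  expect_equal(boundary_rate_function(0, 68.5, "N", width = 10, peak = 12), 12)
  expect_lt(boundary_rate_function(0, 0, "N", width = 10, peak = 12), 0.1)
  # wall-tracking: after a 70-degree rotation the field centroid stays along
  # the same wall in platform coordinates
  bt <- boundary_truth("N", width = 12, peak = 10)
  s70 <- scene_config("ROT70")
  rf <- gridframes:::session_rate_function(bt, scene_config("STD"), s70)
  g <- expand.grid(x = seq(-65, 65, 2), y = seq(-65, 65, 2))
  p <- gridframes:::rotate_cw(g$x, g$y, -s70$platform_rotation)
  inside <- abs(p$x) <= 68.5 & abs(p$y) <= 68.5
  rate <- rf$fn(g$x, g$y)[inside]
  wall_dist <- (68.5 - p$y)[inside]   # platform-frame distance to the N wall
  centroid <- sum(rate * wall_dist) / sum(rate)
  expect_lt(centroid, 12)
})
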