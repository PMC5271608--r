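test_that("crosscorrelograms equal brute-force summation on small maps", {
  for (seed in c(1, 2)) {
    a <- random_map(12, 10, seed = seed)
    b <- random_map(12, 10, seed = seed + 100)
    cg <- crosscorrelogram(a, b, min_overlap = 5)
    oracle <- bf_crosscorrelogram(ifelse(a$occupied, a$rate, NA),
                                  ifelse(b$occupied, b$rate, NA),
                                  min_overlap = 5)
    expect_equal(dim(cg$r), dim(oracle))
    expect_lt(max(abs(cg$r - oracle), na.rm = TRUE), 1e-10)
    expect_identical(is.na(cg$r), is.na(oracle))
  }
  expect_error(crosscorrelogram(random_map(5, 5, 1, bin_size = 3),
                                random_map(5, 5, 1, bin_size = 2)),
               "bin sizes")
})

test_that("overlap below the 100-bin minimum invalidates a displacement", {
  a <- random_map(25, 5, seed = 3, na_frac = 0)
  cg <- crosscorrelogram(a, a, min_overlap = 100)
  i0 <- which(cg$dx == 0); j0 <- which(cg$dy == 0)
  expect_equal(cg$r[i0, j0], 1)                      # zero displacement: r = 1
  expect_false(is.na(cg$r[i0 + 5, j0]))              # overlap 100: valid
  expect_true(is.na(cg$r[i0 + 6, j0]))               # overlap 95: invalid
})

test_that("autocorrelograms are exactly point-symmetric with unit center", {
  m <- random_map(14, 14, seed = 7)
  ac <- autocorrelogram(m, min_overlap = 20)
  rev2 <- function(x) x[rev(seq_len(nrow(x))), rev(seq_len(ncol(x)))]
  expect_identical(ac$r, rev2(ac$r))
  expect_equal(ac$r[which(ac$dx == 0), which(ac$dy == 0)], 1)
})

test_that("correlation fields require 20 contiguous bins above r = 0.1", {
  blank <- structure(list(r = matrix(0.05, 21, 21), valid = matrix(TRUE, 21, 21),
                          dx = -10:10, dy = -10:10, bin_size = 3),
                     class = "gf_correlogram")
  expect_equal(nrow(detect_fields(blank)), 0)
  # a 19-bin component is excluded; a 20-bin one is kept
  r <- matrix(0, 21, 21)
  r[2:20, 2] <- 0.5            # 19 contiguous bins
  r[2:21, 6] <- 0.5            # 20 contiguous bins
  cg <- structure(list(r = r, valid = matrix(TRUE, 21, 21),
                       dx = -10:10, dy = -10:10, bin_size = 3),
                  class = "gf_correlogram")
  f <- detect_fields(cg)
  expect_equal(nrow(f), 1)
  expect_equal(f$area, 20)
  # ideal grid: central field plus at least 6 surrounding fields
  fa <- detect_fields(autocorrelogram(ideal_grid_map(scale = 60)))
  expect_gte(nrow(fa), 7)
  expect_true(fa$central[1] && fa$dist[1] < 3)
})

test_that("canonical axes follow the abscissa-first, CCW/CW convention", {
  g0 <- grid_geometry(ideal_grid_map(scale = 60, orientation = 0))
  expect_equal(g0$axes$ax0, 0, tolerance = 1)
  expect_equal(g0$axes$ax1, -60, tolerance = 1)   # first CCW of +x (CW-positive)
  expect_equal(g0$axes$ax2, 60, tolerance = 1)
  expect_lt(abs(g0$orientation), 1)
  g7 <- grid_geometry(ideal_grid_map(scale = 60, orientation = 7))
  expect_equal(g7$orientation, 7, tolerance = 1.5)
  # exact +/-30 tie resolves to the CCW candidate
  fields <- data.frame(field = 1:7,
                       com_x = c(0, 60 * cospi(c(30, 90, 150, -150, -90, -30) / 180)),
                       com_y = c(0, 60 * sinpi(c(-30, -90, -150, 150, 90, 30) / 180)),
                       area = 25)
  fields$dist <- sqrt(fields$com_x^2 + fields$com_y^2)
  fields$central <- c(TRUE, rep(FALSE, 6))
  ax <- canonical_axes(fields)
  expect_equal(ax$ax0, -30)
})

test_that("grid scale is homogeneous and rotation-invariant", {
  g60 <- grid_geometry(ideal_grid_map(scale = 60))
  expect_equal(g60$scale, 60, tolerance = 3)
  g45 <- grid_geometry(ideal_grid_map(scale = 45))
  g90 <- grid_geometry(ideal_grid_map(scale = 90))
  expect_equal(g90$scale / g45$scale, 2, tolerance = 0.05)
  # rotating the map leaves scale unchanged and adds to orientation (mod 60)
  rot <- rotate_ratemap(ideal_grid_map(scale = 60, orientation = 7), 13)
  grot <- grid_geometry(rot)
  expect_equal(grot$scale, g60$scale, tolerance = 1.5)
  expect_equal(wrap_grid_angle(grot$orientation - 7 - 13), 0, tolerance = 1)
})

test_that("elliptical index is 1 - B/A of the fitted inner-vertex ellipse", {
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  mk_fields <- function(x, y) {
    f <- data.frame(field = 1:7, com_x = c(0, x), com_y = c(0, y), area = 25)
    f$dist <- sqrt(f$com_x^2 + f$com_y^2)
    f$central <- c(TRUE, rep(FALSE, 6))
    f
  }
  circ <- fit_ellipse_index(mk_fields(50 * cos(th), 50 * sin(th)))
  expect_equal(circ$index, 0, tolerance = 1e-9)
  ell <- fit_ellipse_index(mk_fields(60 * cos(th), 30 * sin(th)))
  expect_equal(ell$index, 0.5, tolerance = 1e-9)
  expect_error(fit_ellipse_index(mk_fields(50 * cos(th), 50 * sin(th))[1:5, ]),
               "degenerate")
  # sheared lattice: measured index matches the analytic singular-value ratio
  shear <- matrix(c(1, 0.25, 0, 1), 2)   # x' = x, y' = 0.25 x + y
  sv <- svd(shear)$d
  expected <- 1 - sv[2] / sv[1]
  hex <- rbind(50 * cos(th), 50 * sin(th))
  pts <- shear %*% hex
  sheared <- fit_ellipse_index(mk_fields(pts[1, ], pts[2, ]))
  expect_equal(sheared$index, expected, tolerance = 0.02)
})
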