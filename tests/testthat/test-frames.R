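test_that("grid angular space wraps physical rotations as published", {
  expect_equal(to_grid_angle(70), 10)
  expect_equal(to_grid_angle(45), -15)
  expect_equal(to_grid_angle(0), 0)
  expect_equal(geometric_frame_angle(70), -20)
  expect_equal(geometric_frame_angle(20), 20)
  expect_equal(geometric_frame_angle(45), 15)   # tie resolved opposite in sign
  expect_equal(geometric_frame_angle(-45), -15)
})

test_that("grid-angle arithmetic agrees with exhaustive enumeration", {
  brute_wrap <- function(a) {
    cand <- a - 60 * (-7:7)
    cand[cand >= -30 & cand < 30][1]
  }
  for (a in -180:180) expect_equal(wrap_grid_angle(a), brute_wrap(a))
  brute_cong <- function(a) {
    cand <- a - 90 * (-5:5)
    cand <- cand[abs(cand) <= 45]
    if (length(cand) == 2) cand <- cand[sign(cand) != sign(a)]
    cand[which.min(abs(cand))]
  }
  for (a in -180:180) expect_equal(congruent_square_rotation(a), brute_cong(a))
})

test_that("rotations between sessions and frames follow the sign conventions", {
  expect_equal(grid_rotation(5, 5), 0)
  expect_equal(grid_rotation(5, 19), 14)
  expect_equal(grid_rotation(28, -28), 4)    # wraparound
  expect_equal(rotation_in_frame(14, to_grid_angle(20)), -6)  # ROT20 undershoot
  expect_equal(rotation_in_frame(14, 0), 14)
  expect_equal(rotation_in_frame(6, to_grid_angle(70)), -4)
  expect_equal(rotation_in_frame(6, geometric_frame_angle(70)), 26)
})

test_that("phase shifts are read off the rotation-adjusted crosscorrelogram", {
  m <- ideal_grid_map(scale = 60, orientation = 7, phase = c(5, -3))
  expect_equal(phase_shift_maps(m, m, 0), c(0, 0), tolerance = 3)
  shifted <- ideal_grid_map(scale = 60, orientation = 7, phase = c(11, 0))
  expect_equal(phase_shift_maps(m, shifted, 0), c(6, 3), tolerance = 1.5)
  expect_error(phase_shift_maps(m, ideal_grid_map(scale = 60, orientation = 7,
                                                  peak_rate = 0) , 0),
               "degenerate|field")
})

test_that("translation-phase algebra matches closed forms and a lattice oracle", {
  expect_equal(shift_alpha(68.5, 0), 0)
  expect_equal(shift_alpha(137, 0), pi)
  expect_error(shift_alpha(60, 95), "positive")
  expect_error(shift_alpha(-3, 0), "positive")
  # oracle: minimal-magnitude residue of 68.5 over the projected period
  lattice_oracle <- function(scale, orientation, translation = 68.5) {
    Tx <- scale * cos(orientation * pi / 180)
    res <- translation - Tx * round(translation / Tx)
    2 * pi * res / Tx
  }
  for (p in list(c(60, 10), c(85, 0), c(52, 22))) {
    expect_equal(shift_alpha(p[1], p[2]), lattice_oracle(p[1], p[2]),
                 tolerance = 1e-9)
  }
  # beta = alpha gives zero room shift
  a <- shift_alpha(60, 10)
  Tx <- 60 * cos(10 * pi / 180)
  expect_equal(room_phase_shift(a * Tx / (2 * pi), 60, 10), 0, tolerance = 1e-9)
  # exact multiple of the period: alpha = 0
  expect_equal(room_phase_shift(0, 34.25, 0), 0)
  # platform-anchored grid, scale 100: residue of 68.5 to the nearest multiple
  expect_equal(abs(room_phase_shift(0, 100, 0)), 31.5, tolerance = 1e-9)
})

test_that("noise-free frame decomposition recovers every anchoring policy", {
  std <- scene_config("STD")
  cases <- list(
    list(anch = "platform", manip = "ROT20", under = 6, frame = "platform",
         rot = -6, room_rot = 14),
    list(anch = "platform", manip = "ROT70", under = 0, frame = "platform",
         rot = 0, room_rot = 10),
    list(anch = "geometry", manip = "ROT70", under = 0, frame = "geometry",
         rot = 0, room_rot = -20),
    list(anch = "geometry", manip = "ROT45", under = 0, frame = "geometry",
         rot = 0, room_rot = 15),
    list(anch = "room", manip = "ROT70", under = 0, frame = "room",
         rot = 0, room_rot = 0))
  for (cs in cases) {
    truth <- grid_truth(scale = 60, orientation = 7, phase = c(5, -3),
                        anchoring = cs$anch, under_rotation = cs$under)
    sm <- scene_config(cs$manip)
    tm <- apply_manipulation(truth, std, sm)
    ext <- map_extent(137, sm$platform_rotation, 3)
    m_std <- ratemap_from_function(truth, ext, std)
    m_m <- ratemap_from_function(tm, ext, sm)
    g_std <- grid_geometry(m_std); g_m <- grid_geometry(m_m)
    expect_equal(grid_rotation(g_std, g_m), cs$room_rot, tolerance = 1)
    fr <- frame_response(m_std, m_m, g_std, g_m, cs$frame, sm)
    expect_equal(fr$rotation, cs$rot, tolerance = 1)
    expect_lt(fr$shift_magnitude, 3)   # anchored: no phase shift in its frame
  }
})

test_that("SHIFT phase decomposition separates room from platform anchoring", {
  std <- scene_config("STD"); sh <- scene_config("SHIFT")
  ext <- map_extent(137, 0, 3)
  # room-anchored: platform shift ~ alpha residue, room shift ~ 0
  roomt <- grid_truth(scale = 60, orientation = 0, phase = c(5, -3),
                      anchoring = "room")
  tm <- apply_manipulation(roomt, std, sh)
  m_std <- ratemap_from_function(roomt, ext, std)
  m_sh <- ratemap_from_function(tm, ext, sh)
  g_std <- grid_geometry(m_std); g_sh <- grid_geometry(m_sh)
  fr_room <- frame_response(m_std, m_sh, g_std, g_sh, "room", sh)
  fr_plat <- frame_response(m_std, m_sh, g_std, g_sh, "platform", sh)
  expect_lt(abs(fr_room$shift[1]), 2)
  alpha_cm <- shift_alpha(g_std$scale, g_std$orientation) * g_std$scale / (2 * pi)
  expect_equal(abs(fr_plat$shift[1]), abs(alpha_cm), tolerance = 1.5)
  # frame-consistency: platform minus room shift is the alpha residue (mod T)
  Tx <- g_std$scale * cos(g_std$orientation * pi / 180)
  resid <- (fr_plat$shift[1] - fr_room$shift[1]) + alpha_cm
  expect_equal(resid - Tx * round(resid / Tx), 0, tolerance = 1.5)
  # platform-anchored: platform shift ~ 0, room shift the alpha residue
  platt <- grid_truth(scale = 60, orientation = 0, phase = c(5, -3),
                      anchoring = "platform")
  tmp <- apply_manipulation(platt, std, sh)
  m_shp <- ratemap_from_function(tmp, ext, sh)
  g_shp <- grid_geometry(m_shp)
  fp_plat <- frame_response(m_std, m_shp, g_std, g_shp, "platform", sh)
  fp_room <- frame_response(m_std, m_shp, g_std, g_shp, "room", sh)
  expect_lt(abs(fp_plat$shift[1]), 2)
  expect_equal(abs(fp_room$shift[1]), abs(alpha_cm), tolerance = 1.5)
})
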