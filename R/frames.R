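# Rotation/phase decomposition of a grid's response to a platform
# manipulation against the room, physical-platform and geometric (square
# symmetry) reference frames.

#' Grid-angular-space equivalent of a physical platform rotation
#'
#' Because of the grid's 60-degree symmetry, any physical rotation is
#' equivalent to its representative in the circular \[-30, +30) range: a
#' 70-degree CW platform rotation is a +10-degree rotation in grid angular
#' space, 45 CW is -15 (15 CCW).
#'
#' @param rotation physical rotation, degrees CW.
#' @return grid angle, degrees CW in \[-30, 30).
#' @export
to_grid_angle <- function(rotation) wrap_grid_angle(rotation)

#' Geometric-reference-frame angle of a platform rotation
#'
#' The geometric frame is the 90-degree-symmetric configuration of the
#' square platform implying the smallest rotation with respect to the room
#' (see [congruent_square_rotation()]), expressed in grid angular space:
#' ROT70 gives -20 (20 CCW), ROT45 gives +15.
#'
#' @param rotation physical platform rotation, degrees CW.
#' @return grid angle, degrees CW in \[-30, 30).
#' @export
geometric_frame_angle <- function(rotation) {
  wrap_grid_angle(congruent_square_rotation(rotation))
}

#' Grid rotation between two sessions, in the room frame
#'
#' Difference of grid orientation between the STD and manipulated sessions,
#' wrapped into grid angular space. Positive = clockwise.
#'
#' @param std_geom,m_geom [grid_geometry()] results of the STD and
#'   manipulated maps (both must be valid), or bare orientations in degrees.
#' @return rotation, degrees CW in \[-30, 30).
#' @export
grid_rotation <- function(std_geom, m_geom) {
  ori <- function(g) {
    if (inherits(g, "gf_gridgeom")) {
      if (!g$ok) stop("grid rotation requires classified (valid) geometry")
      g$orientation
    } else g
  }
  wrap_grid_angle(ori(m_geom) - ori(std_geom))
}

#' Grid rotation relative to a reference frame
#'
#' Subtracts the frame's rotation (in grid angular space) from the measured
#' room rotation: positive values are over-rotations, negative values
#' under-rotations of the grid with respect to that frame.
#'
#' @param room_rotation measured grid rotation in the room, degrees
#'   (\[-30, 30)).
#' @param frame_angle the frame's grid-angular rotation ([to_grid_angle()] or
#'   [geometric_frame_angle()]).
#' @return rotation, degrees CW in \[-30, 30).
#' @export
rotation_in_frame <- function(room_rotation, frame_angle) {
  wrap_grid_angle(room_rotation - frame_angle)
}

# physical rotation that aligns the STD map with a frame
frame_physical_rotation <- function(frame, scene_m) {
  switch(frame,
         room = 0,
         platform = scene_m$platform_rotation,
         geometry = congruent_square_rotation(scene_m$platform_rotation),
         stop("unknown frame: ", frame))
}

#' Phase shift between two rate maps after rotational alignment
#'
#' Rotates the STD rate map by `rotation` (the frame's physical rotation
#' plus the grid's residual rotation in that frame; for the room frame just
#' the measured room rotation), computes the crosscorrelogram with the
#' manipulated map, and returns the displacement of the center of mass of
#' the most central correlation field from the center.
#'
#' @param std_map,m_map smoothed `gf_ratemap`s on a common grid.
#' @param rotation rotation applied to the STD map, degrees CW.
#' @param cfg [gf_config()].
#' @return shift vector (x, y), cm.
#' @export
phase_shift_maps <- function(std_map, m_map, rotation, cfg = gf_config()) {
  rot <- if (abs(rotation) > 1e-9) rotate_ratemap(std_map, rotation) else std_map
  cg <- crosscorrelogram(rot, m_map, cfg$min_overlap)
  fl <- detect_fields(cg, cfg$field_r_thresh, cfg$field_min_bins)
  if (nrow(fl) == 0) stop("degenerate geometry: no central correlation field")
  c(fl$com_x[1], fl$com_y[1])
}

#' Translation-phase algebra for SHIFT sessions
#'
#' For a half-platform translation (68.5 cm for the 137-cm platform), the
#' platform-frame phase shift expected of a perfectly room-anchored grid is
#' the remainder of the translation over the grid period projected on the
#' translation (x) axis, as a phase in radians:
#' alpha = 2 pi 68.5 / (scale cos(orientation)), normalized to (-pi, pi].
#' The observed platform-frame shift maps to beta analogously, and
#' gamma = beta - alpha (normalized) is the phase seen in the room frame;
#' in cm: room shift = gamma scale cos(orientation) / (2 pi).
#'
#' @param platform_shift_x observed platform-frame phase shift along the
#'   translation axis, cm, signed as the displacement of the STD pattern
#'   relative to the manipulated map (a perfectly room-anchored grid then
#'   has beta = alpha, hence zero room shift).
#' @param scale grid scale, cm.
#' @param orientation grid orientation, degrees (|orientation| < 90).
#' @param translation platform translation magnitude, cm.
#' @return `gf_shiftphase`: list(alpha, beta, gamma (rad), room_shift (cm)).
#' @export
shift_phase <- function(platform_shift_x, scale, orientation,
                        translation = 68.5) {
  a <- shift_alpha(scale, orientation, translation)
  period <- scale * cos(orientation * pi / 180)
  b <- wrap_pi(2 * pi * platform_shift_x / period)
  g <- wrap_pi(b - a)
  structure(list(alpha = a, beta = b, gamma = g,
                 room_shift = g * period / (2 * pi)),
            class = "gf_shiftphase")
}

#' @rdname shift_phase
#' @export
shift_alpha <- function(scale, orientation, translation = 68.5) {
  if (scale <= 0) stop("scale must be positive")
  co <- cos(orientation * pi / 180)
  if (co <= 0) stop("cos(orientation) must be positive")
  wrap_pi(2 * pi * translation / (scale * co))
}

#' @rdname shift_phase
#' @export
room_phase_shift <- function(platform_shift_x, scale, orientation,
                             translation = 68.5) {
  shift_phase(platform_shift_x, scale, orientation, translation)$room_shift
}

# wrap radians into (-pi, pi]
wrap_pi <- function(a) a - 2 * pi * ceiling((a - pi) / (2 * pi))

#' Rotation and phase response of a grid in one reference frame
#'
#' @param std_map,m_map smoothed maps of the STD and manipulated sessions on
#'   a common grid.
#' @param std_geom,m_geom their [grid_geometry()] (valid).
#' @param frame "room", "platform" or "geometry".
#' @param scene_m [scene_config()] of the manipulated session.
#' @param cfg [gf_config()].
#' @return `gf_frameresponse`: list(frame, rotation (deg, \[-30, 30)),
#'   shift (x, y cm), shift_magnitude, phase_fraction).
#' @export
frame_response <- function(std_map, m_map, std_geom, m_geom, frame, scene_m,
                           cfg = gf_config()) {
  room_rot <- grid_rotation(std_geom, m_geom)
  phys <- frame_physical_rotation(frame, scene_m)
  rot_frame <- rotation_in_frame(room_rot, wrap_grid_angle(phys))
  if (scene_m$manipulation == "SHIFT") {
    # both maps are platform-centered; the rotation-adjusted crosscorrelogram
    # yields the platform/geometric phase shift directly
    shift_p <- phase_shift_maps(std_map, m_map, room_rot, cfg)
    shift <- if (frame == "room") {
      # the correlogram displacement is the manipulated pattern relative to
      # STD; the translation algebra is defined for the opposite sign, so
      # flip on the way in and out
      sp <- shift_phase(-shift_p[1], std_geom$scale, std_geom$orientation,
                        cfg$shift_translation)
      c(-sp$room_shift, shift_p[2])
    } else shift_p
    rot_out <- room_rot   # frames are directionally aligned in SHIFT
  } else {
    shift <- phase_shift_maps(std_map, m_map, phys + rot_frame, cfg)
    rot_out <- rot_frame
  }
  mag <- sqrt(sum(shift^2))
  structure(list(frame = frame, rotation = rot_out, shift = shift,
                 shift_magnitude = mag,
                 phase_fraction = mag / std_geom$scale),
            class = "gf_frameresponse")
}

#' Frame responses of one unit across the three reference frames
#'
#' @inheritParams frame_response
#' @param frames frames to evaluate.
#' @return data.frame (frame, rotation, shift_x, shift_y, shift_magnitude,
#'   phase_fraction).
#' @export
grid_frame_responses <- function(std_map, m_map, std_geom, m_geom, scene_m,
                                 frames = c("room", "platform", "geometry"),
                                 cfg = gf_config()) {
  rows <- lapply(frames, function(fr) {
    r <- frame_response(std_map, m_map, std_geom, m_geom, fr, scene_m, cfg)
    data.frame(frame = fr, rotation = r$rotation, shift_x = r$shift[1],
               shift_y = r$shift[2], shift_magnitude = r$shift_magnitude,
               phase_fraction = r$phase_fraction)
  })
  do.call(rbind, rows)
}
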