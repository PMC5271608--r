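#' Scene configuration for one recording session
#'
#' Describes the platform placement for a session: a square foraging platform
#' inside a cue-rich room, either in the standard position (STD / STD2), or
#' rotated clockwise (ROT20/30/45/70), or translated along x by half its side
#' (SHIFT). Coordinates are cm in the analysis frame: room-axis-aligned,
#' origin at the platform center (the camera is re-centered on the platform
#' in SHIFT, as in the recordings).
#'
#' @param manipulation one of "STD", "ROT20", "ROT30", "ROT45", "ROT70",
#'   "SHIFT", "STD2".
#' @param platform_side platform side, cm.
#' @param room_size room (length, width), cm; the platform must fit at any
#'   rotation.
#' @param frame_rate tracking frame rate, Hz.
#' @return object of class `gf_scene`.
#' @export
scene_config <- function(manipulation = "STD", platform_side = 137,
                         room_size = c(355, 280), frame_rate = 30) {
  manips <- c(STD = 0, ROT20 = 20, ROT30 = 30, ROT45 = 45, ROT70 = 70,
              SHIFT = 0, STD2 = 0)
  if (!manipulation %in% names(manips))
    stop("unknown manipulation label: ", manipulation)
  if (platform_side <= 0) stop("platform_side must be positive")
  if (platform_side * sqrt(2) > min(room_size))
    stop("platform does not fit in the room at all rotations")
  rot <- unname(manips[manipulation])
  trans <- if (manipulation == "SHIFT") c(platform_side / 2, 0) else c(0, 0)
  structure(list(manipulation = manipulation, platform_side = platform_side,
                 room_size = room_size, platform_rotation = rot,
                 translation_vector = trans, frame_rate = frame_rate),
            class = "gf_scene")
}

#' Ground-truth parameters of a simulated grid cell
#'
#' @param scale vertex spacing, cm (> 0).
#' @param orientation grid orientation, degrees clockwise (60-degree
#'   periodic).
#' @param phase lattice offset (x, y), cm.
#' @param peak_rate firing rate at a lattice vertex, Hz.
#' @param anchoring which reference frame the cell follows under platform
#'   manipulations: "room", "platform" or "geometry" (the platform's square
#'   symmetry class with minimal rotation).
#' @param under_rotation configured rotational undershoot, degrees, in
#'   (-30, 30): the grid rotates by this much less than its anchor.
#' @param phase_lag configured translational lag (x, y), cm, added after the
#'   anchor's transform.
#' @param elliptical_index_target distortion 1 - B/A injected by an affine
#'   compression of positions before rate evaluation (0 = perfect hexagon).
#' @param ellipse_axis_angle direction (deg CW from +x) of the compressed
#'   (short) lattice axis when distortion is injected.
#' @param model "cosine" (rectified sum of three plane waves, the default) or
#'   "gaussian" (Gaussian bumps on the lattice), for robustness checks.
#' @param field_sigma Gaussian field width, fraction of scale (gaussian model
#'   only).
#' @param rectify_thresh rectification level of the cosine model, in the
#'   three-cosine sum's \[-1.5, 3\] range: rate is proportional to
#'   max(sum - rectify_thresh, 0). The default 1.25 gives firing fields
#'   covering roughly a fifth of the platform, as in real grid cells;
#'   0 gives the broad-field variant.
#' @return object of class `gf_gridtruth`.
#' @export
grid_truth <- function(scale = 60, orientation = 0, phase = c(0, 0),
                       peak_rate = 15, anchoring = c("platform", "room", "geometry"),
                       under_rotation = 0, phase_lag = c(0, 0),
                       elliptical_index_target = 0, ellipse_axis_angle = 0,
                       model = c("cosine", "gaussian"), field_sigma = 0.16,
                       rectify_thresh = 1.25) {
  anchoring <- match.arg(anchoring)
  model <- match.arg(model)
  if (rectify_thresh < 0 || rectify_thresh >= 3)
    stop("rectify_thresh must lie in [0, 3)")
  if (!is.finite(scale) || scale <= 0) stop("grid scale must be positive")
  if (under_rotation <= -30 || under_rotation >= 30)
    stop("under_rotation must lie in (-30, 30)")
  if (elliptical_index_target < 0 || elliptical_index_target >= 1)
    stop("elliptical_index_target must lie in [0, 1)")
  structure(list(scale = scale, orientation = orientation, phase = phase,
                 peak_rate = peak_rate, anchoring = anchoring,
                 under_rotation = under_rotation, phase_lag = phase_lag,
                 elliptical_index_target = elliptical_index_target,
                 ellipse_axis_angle = ellipse_axis_angle,
                 model = model, field_sigma = field_sigma,
                 rectify_thresh = rectify_thresh),
            class = "gf_gridtruth")
}

# unit vector of a clockwise angle (deg), y axis up
dir_cw <- function(a) c(cos(a * pi / 180), -sin(a * pi / 180))

#' Ideal grid-cell firing rate at given positions
#'
#' Hexagonal-lattice rate model. The default is a rectified sum of three
#' plane-wave cosines with wavevectors 60 degrees apart, scaled so the rate
#' is `peak_rate` at lattice vertices and 0 between fields; the alternative
#' places Gaussian bumps on the lattice vertices. The function is periodic
#' under any lattice vector of the hexagonal lattice defined by
#' (scale, orientation, phase).
#'
#' @param x,y positions, cm (vectors of equal length).
#' @param truth a [grid_truth()] object.
#' @return firing rate(s), Hz.
#' @export
grid_rate_function <- function(x, y, truth) {
  if (!inherits(truth, "gf_gridtruth")) stop("truth must be a gf_gridtruth")
  px <- x - truth$phase[1]
  py <- y - truth$phase[2]
  e <- truth$elliptical_index_target
  if (e > 0) {
    # compress positions along the chosen axis -> lattice shrinks along it
    u <- dir_cw(truth$ellipse_axis_angle)
    s <- 1 / (1 - e)
    proj <- px * u[1] + py * u[2]
    px <- px + (s - 1) * proj * u[1]
    py <- py + (s - 1) * proj * u[2]
  }
  if (truth$model == "cosine") {
    kmag <- 4 * pi / (sqrt(3) * truth$scale)
    acc <- 0
    for (j in 0:2) {
      u <- dir_cw(truth$orientation + 30 + 60 * j)
      acc <- acc + cos(kmag * (px * u[1] + py * u[2]))
    }
    rt <- truth$rectify_thresh %||% 0
    truth$peak_rate * pmax(acc - rt, 0) / (3 - rt)
  } else {
    a1 <- truth$scale * dir_cw(truth$orientation)
    a2 <- truth$scale * dir_cw(truth$orientation + 60)
    M <- cbind(a1, a2)
    Minv <- solve(M)
    n1 <- Minv[1, 1] * px + Minv[1, 2] * py
    n2 <- Minv[2, 1] * px + Minv[2, 2] * py
    best <- rep(Inf, length(px))
    for (d1 in -1:1) for (d2 in -1:1) {
      m1 <- round(n1) + d1; m2 <- round(n2) + d2
      vx <- M[1, 1] * m1 + M[1, 2] * m2
      vy <- M[2, 1] * m1 + M[2, 2] * m2
      best <- pmin(best, (px - vx)^2 + (py - vy)^2)
    }
    sig <- truth$field_sigma * truth$scale
    truth$peak_rate * exp(-best / (2 * sig^2))
  }
}

#' Boundary-cell firing rate
#'
#' Fires at `peak` within `width` of one platform wall (in platform
#' coordinates), decaying as a half-Gaussian beyond it.
#'
#' @param x,y positions, cm, platform frame (origin at center).
#' @param wall one of "N" (y = +side/2), "S", "E" (x = +side/2), "W".
#' @param width cm of full-rate band along the wall (> 0).
#' @param peak peak rate, Hz.
#' @param platform_side platform side, cm.
#' @return firing rate(s), Hz.
#' @export
boundary_rate_function <- function(x, y, wall = c("N", "S", "E", "W"),
                                   width = 12, peak = 10, platform_side = 137) {
  wall <- match.arg(wall)
  if (width <= 0) stop("width must be positive")
  half <- platform_side / 2
  d <- switch(wall, N = half - y, S = y + half, E = half - x, W = x + half)
  ifelse(d <= width, peak, peak * exp(-(d - width)^2 / (2 * (width / 2)^2)))
}

#' Motion-model parameters for the trajectory simulator
#'
#' The paper-style foraging is emulated by a smoothed random walk: speed
#' relaxes toward a per-epoch target, heading diffuses, walls reflect, and
#' explicit pause states (speed ~ 0 for > 500 ms) occur at a configured rate.
#' Defaults were chosen once as plausible rat foraging values; they are free
#' parameters of the generator.
#'
#' @param mean_speed mean of the per-epoch target speed, cm/s.
#' @param speed_sd s.d. of the target speed draw, cm/s.
#' @param relax_tau speed relaxation time constant, s.
#' @param turn_sd heading diffusion, deg/sqrt(s).
#' @param epoch_mean mean duration between target-speed redraws, s.
#' @param pause_rate pause initiations per second of running.
#' @param pause_min,pause_mean minimum and mean additional pause duration, s.
#' @param margin wall reflection margin, cm.
#' @return list of class `gf_motion`.
#' @export
motion_params <- function(mean_speed = 27, speed_sd = 5, relax_tau = 0.5,
                          turn_sd = 40, epoch_mean = 3, pause_rate = 0.03,
                          pause_min = 0.6, pause_mean = 0.5, margin = 1) {
  structure(as.list(environment()), class = "gf_motion")
}

#' Simulate a foraging trajectory on the platform
#'
#' Positions are in platform coordinates (origin at platform center); use
#' [simulate_session()] to place them in the analysis frame of a manipulated
#' session. Identical (parameters, seed) give identical output.
#'
#' @param duration session length, s (>= 0).
#' @param scene a [scene_config()].
#' @param motion a [motion_params()].
#' @param seed integer seed.
#' @return `gf_trajectory`: data.frame (t, x, y) with attribute
#'   `frame_rate`.
#' @export
simulate_trajectory <- function(duration, scene = scene_config(),
                                motion = motion_params(), seed = 1) {
  if (!is.finite(duration) || duration < 0) stop("duration must be non-negative")
  fr <- scene$frame_rate
  n <- floor(duration * fr)
  half <- scene$platform_side / 2 - motion$margin
  out_t <- seq_len(n) / fr - 1 / fr
  if (n == 0) {
    traj <- data.frame(t = numeric(0), x = numeric(0), y = numeric(0))
    attr(traj, "frame_rate") <- fr
    class(traj) <- c("gf_trajectory", "data.frame")
    return(traj)
  }
  with_seed(seed, {
    dt <- 1 / fr
    x <- numeric(n); y <- numeric(n)
    px <- stats::runif(1, -half, half); py <- stats::runif(1, -half, half)
    heading <- stats::runif(1, 0, 360)
    vt <- max(8, stats::rnorm(1, motion$mean_speed, motion$speed_sd))
    v <- vt
    epoch_left <- stats::rexp(1, 1 / motion$epoch_mean)
    pause_left <- 0
    for (i in seq_len(n)) {
      if (pause_left > 0) {
        pause_left <- pause_left - dt
        v <- stats::runif(1, 0, 1)   # residual jitter, below immobility threshold
      } else {
        if (stats::runif(1) < motion$pause_rate * dt) {
          pause_left <- motion$pause_min + stats::rexp(1, 1 / motion$pause_mean)
        }
        epoch_left <- epoch_left - dt
        if (epoch_left <= 0) {
          vt <- max(8, stats::rnorm(1, motion$mean_speed, motion$speed_sd))
          epoch_left <- stats::rexp(1, 1 / motion$epoch_mean)
        }
        v <- v + (vt - v) * dt / motion$relax_tau +
          stats::rnorm(1, 0, motion$speed_sd * sqrt(dt) / 2)
        v <- max(v, 0)
      }
      heading <- heading + stats::rnorm(1, 0, motion$turn_sd * sqrt(dt))
      step <- v * dt
      nx <- px + step * cos(heading * pi / 180)
      ny <- py + step * sin(heading * pi / 180)
      # reflective walls (heading folded so the walk continues inward)
      if (nx > half)  { nx <- 2 * half - nx;  heading <- 180 - heading }
      if (nx < -half) { nx <- -2 * half - nx; heading <- 180 - heading }
      if (ny > half)  { ny <- 2 * half - ny;  heading <- -heading }
      if (ny < -half) { ny <- -2 * half - ny; heading <- -heading }
      px <- min(max(nx, -half), half); py <- min(max(ny, -half), half)
      x[i] <- px; y[i] <- py
    }
    traj <- data.frame(t = out_t, x = x, y = y)
    attr(traj, "frame_rate") <- fr
    class(traj) <- c("gf_trajectory", "data.frame")
    traj
  })
}

#' Generate spikes from a trajectory by inhomogeneous-Poisson thinning
#'
#' Homogeneous Poisson candidates at `rate_max` over the trajectory time span
#' are thinned with probability rate/rate_max, with positions linearly
#' interpolated between frames.
#'
#' @param traj a `gf_trajectory`.
#' @param rate_fn function(x, y) -> rate Hz (vectorized, bounded by
#'   `rate_max`).
#' @param seed integer seed.
#' @param rate_max known upper bound of `rate_fn` on the platform, Hz.
#' @return `gf_spiketrain`: list with sorted `times` (s) and `unit` metadata.
#' @export
generate_spikes <- function(traj, rate_fn, seed = 1, rate_max) {
  if (missing(rate_max) || !is.finite(rate_max) || rate_max < 0)
    stop("rate_max must be a known finite non-negative bound")
  if (nrow(traj) < 2 || rate_max == 0)
    return(spike_train(numeric(0)))
  t0 <- traj$t[1]; t1 <- traj$t[nrow(traj)]
  with_seed(seed, {
    ncand <- stats::rpois(1, rate_max * (t1 - t0))
    tc <- sort(stats::runif(ncand, t0, t1))
    xs <- stats::approx(traj$t, traj$x, tc)$y
    ys <- stats::approx(traj$t, traj$y, tc)$y
    r <- rate_fn(xs, ys)
    if (any(!is.finite(r)) || any(r < 0)) stop("rate function must be finite and non-negative")
    if (any(r > rate_max * (1 + 1e-9))) stop("rate function exceeds rate_max; thinning invalid")
    keep <- stats::runif(ncand) < r / rate_max
    spike_train(tc[keep])
  })
}

#' Smallest platform rotation congruent under the square's 90-degree symmetry
#'
#' Among physical rotations congruent to `rotation` modulo 90 degrees,
#' returns the one of minimal magnitude (degrees CW). The 45-degree tie is
#' resolved toward the congruent rotation opposite in sign to the physical
#' one.
#'
#' @param rotation physical platform rotation, degrees CW.
#' @return congruent rotation in \[-45, 45\], degrees CW.
#' @export
congruent_square_rotation <- function(rotation) {
  c90 <- rotation %% 90
  out <- ifelse(c90 > 45, c90 - 90, c90)
  tie <- abs(c90 - 45) < 1e-12
  out[tie] <- ifelse(rotation[tie] >= 0, -45, 45)
  out
}

#' Ground truth of a grid cell in a manipulated session
#'
#' Expresses the cell's rate function in the analysis frame of the
#' manipulated session, given its anchoring policy: room-anchored cells keep
#' their room-coordinate lattice (the SHIFT camera re-centering makes it
#' appear translated by minus the platform translation); platform-anchored
#' cells rotate/translate with the platform minus the configured
#' under-rotation and phase lag; geometry-anchored cells follow the minimal
#' rotation congruent under the square's symmetry.
#'
#' @param truth STD-session [grid_truth()].
#' @param scene_std STD [scene_config()] (must have manipulation "STD").
#' @param scene_m manipulated-session [scene_config()].
#' @return `gf_gridtruth` for the manipulated session.
#' @export
apply_manipulation <- function(truth, scene_std, scene_m) {
  if (scene_std$manipulation != "STD")
    stop("scene_std must be the STD configuration")
  rho <- scene_m$platform_rotation
  tau <- scene_m$translation_vector
  manipulated <- abs(rho) > 1e-12 || any(abs(tau) > 1e-12)
  out <- truth
  rot_anchor <- switch(truth$anchoring,
    room = 0,
    platform = rho,
    geometry = {
      if (length(scene_m$platform_side) != 1)
        stop("geometry anchoring requires a square platform")
      congruent_square_rotation(rho)
    })
  # the configured undershoot reduces the anchor's rotation toward zero and
  # the lag only manifests when the anchor actually moves
  rot_eff <- rot_anchor - sign(rot_anchor) * truth$under_rotation
  if (truth$anchoring == "room") {
    # pattern fixed in the room; analysis frame follows the platform center
    out$phase <- truth$phase - tau
  } else {
    p <- rotate_cw(truth$phase[1], truth$phase[2], rot_eff)
    out$phase <- c(p$x, p$y) + if (manipulated) truth$phase_lag else c(0, 0)
    out$orientation <- truth$orientation + rot_eff
    out$ellipse_axis_angle <- truth$ellipse_axis_angle + rot_eff
  }
  out
}

#' Simulate one recording session for one cell
#'
#' The trajectory is generated in platform coordinates and mapped into the
#' analysis frame by the platform rotation (the camera is room-aligned and
#' centered on the platform); spikes are drawn from the cell's rate function
#' expressed in that frame.
#'
#' @param truth `gf_gridtruth` already expressed for this session (use
#'   [apply_manipulation()] for manipulated sessions), or a rate function
#'   `function(x, y)`.
#' @param scene this session's [scene_config()].
#' @param duration s.
#' @param seed integer seed.
#' @param motion [motion_params()].
#' @param rate_max bound for thinning; defaults to the truth's `peak_rate`.
#' @return list(traj, spikes, scene) with traj in the analysis frame.
#' @export
simulate_session <- function(truth, scene, duration = 1200, seed = 1,
                             motion = motion_params(), rate_max = NULL) {
  traj_p <- simulate_trajectory(duration, scene, motion, seed = derive_seed(seed, "traj"))
  rp <- rotate_cw(traj_p$x, traj_p$y, scene$platform_rotation)
  traj <- traj_p
  traj$x <- rp$x; traj$y <- rp$y
  if (inherits(truth, "gf_gridtruth")) {
    rate_fn <- function(x, y) grid_rate_function(x, y, truth)
    if (is.null(rate_max)) rate_max <- truth$peak_rate
  } else {
    rate_fn <- truth
    if (is.null(rate_max)) stop("rate_max required for a bare rate function")
  }
  spikes <- generate_spikes(traj, rate_fn, seed = derive_seed(seed, "spikes"),
                            rate_max = rate_max)
  list(traj = traj, spikes = spikes, scene = scene)
}
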