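# Day-level orchestration: simulate -> rate maps -> classification -> frame
# responses -> coupling -> population statistics.

#' Boundary-cell ground truth
#'
#' A wall-tracking boundary cell: its field follows the same geometric
#' boundary of the platform (in platform coordinates) across manipulations.
#'
#' @param wall "N", "S", "E" or "W".
#' @param width full-rate band width, cm.
#' @param peak peak rate, Hz.
#' @return `gf_boundarytruth`.
#' @export
boundary_truth <- function(wall = "N", width = 12, peak = 10) {
  structure(list(wall = wall, width = width, peak = peak),
            class = "gf_boundarytruth")
}

# rate function of a truth object in the analysis frame of a session
session_rate_function <- function(truth, scene_std, scene_m) {
  if (inherits(truth, "gf_gridtruth")) {
    tm <- apply_manipulation(truth, scene_std, scene_m)
    list(fn = function(x, y) grid_rate_function(x, y, tm),
         rate_max = truth$peak_rate, truth = tm)
  } else if (inherits(truth, "gf_boundarytruth")) {
    rho <- scene_m$platform_rotation
    side <- scene_m$platform_side
    list(fn = function(x, y) {
      p <- rotate_cw(x, y, -rho)  # analysis -> platform coordinates
      boundary_rate_function(p$x, p$y, truth$wall, truth$width, truth$peak, side)
    }, rate_max = truth$peak, truth = truth)
  } else if (is.function(truth)) {
    list(fn = truth, rate_max = attr(truth, "rate_max") %||% stop("rate_max attribute required"),
         truth = truth)
  } else stop("unsupported truth object")
}

#' Simulate a full experiment day
#'
#' One trajectory per session (all units are recorded simultaneously),
#' spikes per unit from its anchoring policy's rate function in each
#' session's analysis frame, with the standard-reference resolution used on
#' real days (each manipulated session refers to the most recent preceding
#' STD/STD2).
#'
#' @param truths named list of [grid_truth()] / [boundary_truth()] objects
#'   (STD-session parameters).
#' @param manipulations ordered session labels (first must be "STD").
#' @param duration per-session duration, s.
#' @param seed master seed.
#' @param platform_side cm.
#' @param motion [motion_params()].
#' @return day object: list(day_id, sessions, truths, seed); each session
#'   has session_id, manipulation, scene, traj, spikes (named list),
#'   truth (per-unit session truths) and std_ref.
#' @export
simulate_day <- function(truths,
                         manipulations = c("STD", "ROT20", "ROT70", "SHIFT"),
                         duration = 1200, seed = 1, platform_side = 137,
                         motion = motion_params()) {
  if (manipulations[1] != "STD") stop("the day must start with an STD session")
  scene_std <- scene_config("STD", platform_side)
  sessions <- vector("list", length(manipulations))
  for (si in seq_along(manipulations)) {
    lab <- manipulations[si]
    scene <- scene_config(lab, platform_side)
    traj_p <- simulate_trajectory(duration, scene, motion,
                                  seed = derive_seed(seed, "traj", si, lab))
    rp <- rotate_cw(traj_p$x, traj_p$y, scene$platform_rotation)
    traj <- traj_p; traj$x <- rp$x; traj$y <- rp$y
    spikes <- list(); session_truth <- list()
    for (nm in names(truths)) {
      rf <- session_rate_function(truths[[nm]], scene_std, scene)
      spikes[[nm]] <- generate_spikes(traj, rf$fn,
                                      seed = derive_seed(seed, "spk", si, lab, nm),
                                      rate_max = rf$rate_max)
      session_truth[[nm]] <- rf$truth
    }
    sessions[[si]] <- list(session_id = sprintf("s%02d_%s", si, lab),
                           manipulation = lab, scene = scene, traj = traj,
                           spikes = spikes, truth = session_truth)
  }
  labs <- manipulations
  std_like <- which(labs %in% c("STD", "STD2"))
  for (i in seq_along(sessions)) {
    prior <- std_like[std_like < i]
    sessions[[i]]$std_ref <- if (labs[i] %in% c("STD", "STD2")) NA_integer_
    else max(prior)
  }
  list(day_id = sprintf("synthetic_day_seed%d", seed), sessions = sessions,
       truths = truths, seed = seed)
}

# common map extent covering every session of a day
day_extent <- function(day, bin_size = 3) {
  halfmax <- 0; rot_at_max <- 0; side_at_max <- 137
  for (s in day$sessions) {
    t <- s$scene$platform_rotation * pi / 180
    h <- s$scene$platform_side / 2 * (abs(cos(t)) + abs(sin(t)))
    if (h > halfmax) {
      halfmax <- h; rot_at_max <- s$scene$platform_rotation
      side_at_max <- s$scene$platform_side
    }
  }
  map_extent(side_at_max, rot_at_max, bin_size)
}

#' Run the full analysis over one day
#'
#' Classifies every unit in every session (bootstrap criterion included),
#' decomposes each passing unit's response to each manipulated session into
#' the room / platform / geometry reference frames, measures pairwise
#' coupling with randomized controls, and summarizes rotations per
#' (manipulation, frame) with 60-degree-symmetric circular statistics.
#' Deterministic given `seed`. Units that fail at any stage are logged in
#' the `log` table and the pipeline continues.
#'
#' @param day a day object ([simulate_day()] or [load_day()]).
#' @param cfg [gf_config()].
#' @param seed master seed for bootstraps and controls.
#' @return list of data.frames: classification, frames, pairs, controls,
#'   stats, log.
#' @export
run_day <- function(day, cfg = gf_config(), seed = 1) {
  ext <- day_extent(day, cfg$bin_size)
  cls_rows <- list(); frame_rows <- list(); pair_rows <- list()
  ctrl_rows <- list(); log_rows <- list()
  results <- list()   # [[session_id]][[unit]] = list(map, classification)
  note <- function(...) log_rows[[length(log_rows) + 1]] <<-
    data.frame(message = sprintf(...))
  for (s in day$sessions) {
    results[[s$session_id]] <- list()
    for (nm in names(s$spikes)) {
      r <- tryCatch(
        classify_session(s$traj, s$spikes[[nm]], cfg, ext,
                         seed = derive_seed(seed, "boot", s$session_id, nm)),
        error = function(e) e)
      if (inherits(r, "error")) {
        note("classification failed for %s in %s: %s", nm, s$session_id,
             conditionMessage(r))
        next
      }
      results[[s$session_id]][[nm]] <- r
      cl <- r$classification
      cls_rows[[length(cls_rows) + 1]] <- cbind(
        data.frame(session = s$session_id, manipulation = s$manipulation,
                   unit = nm, gridness = cl$gridness,
                   orientation = cl$geom$orientation, scale = cl$geom$scale,
                   pass = cl$pass,
                   bootstrap_pass_count = cl$bootstrap_pass_count),
        as.data.frame(as.list(cl$criteria)))
    }
  }
  for (si in seq_along(day$sessions)) {
    s <- day$sessions[[si]]
    if (is.na(s$std_ref)) next
    ref <- day$sessions[[s$std_ref]]
    units <- list()
    for (nm in names(s$spikes)) {
      rs <- results[[ref$session_id]][[nm]]
      rm_ <- results[[s$session_id]][[nm]]
      if (is.null(rs) || is.null(rm_)) next
      units[[nm]] <- list(std_map = rs$map, m_map = rm_$map,
                          std_geom = rs$classification$geom,
                          m_geom = rm_$classification$geom,
                          std_pass = rs$classification$pass,
                          m_pass = rm_$classification$pass)
      if (units[[nm]]$std_pass && units[[nm]]$m_pass) {
        fr <- tryCatch(
          grid_frame_responses(rs$map, rm_$map, rs$classification$geom,
                               rm_$classification$geom, s$scene, cfg = cfg),
          error = function(e) e)
        if (inherits(fr, "error")) {
          note("frame response failed for %s in %s: %s", nm, s$session_id,
               conditionMessage(fr))
        } else {
          frame_rows[[length(frame_rows) + 1]] <-
            cbind(data.frame(session = s$session_id,
                             manipulation = s$manipulation, unit = nm), fr)
        }
      }
    }
    pr <- tryCatch(couple_session(units, cfg), error = function(e) e)
    if (inherits(pr, "error")) {
      note("coupling failed in %s: %s", s$session_id, conditionMessage(pr))
    } else if (nrow(pr)) {
      pair_rows[[length(pair_rows) + 1]] <-
        cbind(data.frame(session = s$session_id,
                         manipulation = s$manipulation), pr)
      ct <- control_distributions(units, pr, cfg$n_controls,
                                  seed = derive_seed(seed, "ctrl", s$session_id),
                                  cfg = cfg)
      ctrl_rows[[length(ctrl_rows) + 1]] <-
        cbind(data.frame(session = s$session_id,
                         manipulation = s$manipulation), ct)
    }
  }
  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  frames <- bind(frame_rows,
                 data.frame(session = character(0), manipulation = character(0),
                            unit = character(0), frame = character(0),
                            rotation = numeric(0), shift_x = numeric(0),
                            shift_y = numeric(0), shift_magnitude = numeric(0),
                            phase_fraction = numeric(0)))
  stats_rows <- list()
  if (nrow(frames)) {
    for (key in split(seq_len(nrow(frames)),
                      interaction(frames$manipulation, frames$frame, drop = TRUE))) {
      sub <- frames[key, ]
      mv <- mean_vector(sub$rotation)
      rao_p <- if (nrow(sub) >= cfg$min_circ_n)
        rao_spacing_test(sub$rotation)$p.value else NA_real_
      stats_rows[[length(stats_rows) + 1]] <- data.frame(
        manipulation = sub$manipulation[1], frame = sub$frame[1], n = nrow(sub),
        mean_rotation = mv$direction, vector_length = mv$length,
        mean_shift = mean(sub$shift_magnitude),
        mean_phase_fraction = mean(sub$phase_fraction), rao_p = rao_p)
    }
  }
  list(
    classification = bind(cls_rows, data.frame()),
    frames = frames,
    pairs = bind(pair_rows, data.frame()),
    controls = bind(ctrl_rows, data.frame()),
    stats = bind(stats_rows, data.frame()),
    log = bind(log_rows, data.frame(message = character(0)))
  )
}

#' Packaged synthetic datasets with known ground truth
#'
#' Presets covering the study's main scenarios: a population coherently
#' anchored to the platform (with a 6-degree under-rotation, as in the
#' ROT20 findings), to the room, or to the platform's geometric frame; a
#' bimodal ROT70 population (one mode near -20 degrees following the
#' geometric frame, one near +10 following the platform); and a population
#' whose grid structure degrades selectively in ROT70 (multi-field but
#' non-hexagonal firing).
#'
#' @param preset one of "platform_anchored", "room_anchored",
#'   "geometry_anchored", "bimodal_population", "degraded_rot70".
#' @param seed master seed.
#' @param n_units number of grid cells.
#' @param duration per-session duration, s.
#' @param dir if non-NULL, the dataset (tracking and spike CSVs, YAML
#'   manifest echoing all parameters, ground-truth sidecar) is written
#'   there.
#' @return day object (see [simulate_day()]), invisibly when `dir` is set.
#' @export
make_fixtures <- function(preset = c("platform_anchored", "room_anchored",
                                     "geometry_anchored", "bimodal_population",
                                     "degraded_rot70"),
                          seed = 1, n_units = 8, duration = 1200, dir = NULL) {
  preset <- match.arg(preset)
  scales <- with_seed(derive_seed(seed, "fix-scales", preset),
                      stats::runif(n_units, 50, 90))
  orients <- with_seed(derive_seed(seed, "fix-orients", preset),
                       stats::runif(n_units, 0, 60))
  phases <- with_seed(derive_seed(seed, "fix-phases", preset),
                      matrix(stats::runif(2 * n_units, -30, 30), n_units))
  mk <- function(i, anchoring, under) {
    grid_truth(scale = scales[i], orientation = orients[i],
               phase = phases[i, ], anchoring = anchoring,
               under_rotation = under)
  }
  truths <- switch(preset,
    platform_anchored = lapply(seq_len(n_units), mk, anchoring = "platform", under = 6),
    room_anchored = lapply(seq_len(n_units), mk, anchoring = "room", under = 0),
    geometry_anchored = lapply(seq_len(n_units), mk, anchoring = "geometry", under = 0),
    bimodal_population = lapply(seq_len(n_units), function(i)
      if (i %% 2 == 0) mk(i, "geometry", 2) else mk(i, "platform", 4)),
    degraded_rot70 = lapply(seq_len(n_units), mk, anchoring = "platform", under = 6))
  names(truths) <- sprintf("r1d1t%dc1", seq_len(n_units))
  manips <- switch(preset,
    platform_anchored = c("STD", "ROT20", "ROT70", "SHIFT"),
    room_anchored = c("STD", "ROT20", "ROT70", "SHIFT"),
    c("STD", "ROT70"))
  day <- simulate_day(truths, manips, duration = duration, seed = seed)
  if (preset == "degraded_rot70") {
    # replace ROT70 spike trains: multi-field firing without triangular
    # structure (lattice vertices jittered by ~35% of the scale)
    si <- which(vapply(day$sessions, function(s) s$manipulation, "") == "ROT70")
    s <- day$sessions[[si]]
    for (k in seq_along(truths)) {
      nm <- names(truths)[k]
      deg <- degraded_rate_function(truths[[nm]],
                                    seed = derive_seed(seed, "degrade", nm))
      day$sessions[[si]]$spikes[[nm]] <-
        generate_spikes(s$traj, deg, seed = derive_seed(seed, "spk-deg", nm),
                        rate_max = truths[[nm]]$peak_rate)
      day$sessions[[si]]$truth[[nm]] <- "degraded"
    }
  }
  if (!is.null(dir)) write_fixture_files(day, dir, preset)
  invisible(day)
}

# multi-field rate function with destroyed hexagonal symmetry: Gaussian
# fields at lattice vertices jittered by 0.35 * scale
degraded_rate_function <- function(truth, seed) {
  sc <- truth$scale
  centers <- with_seed(seed, {
    a1 <- sc * dir_cw(truth$orientation)
    a2 <- sc * dir_cw(truth$orientation + 60)
    g <- expand.grid(i = -3:3, j = -3:3)
    cx <- g$i * a1[1] + g$j * a2[1] + stats::rnorm(nrow(g), 0, 0.35 * sc)
    cy <- g$i * a1[2] + g$j * a2[2] + stats::rnorm(nrow(g), 0, 0.35 * sc)
    cbind(cx, cy)
  })
  sig <- 0.16 * sc
  peak <- truth$peak_rate
  function(x, y) {
    best <- rep(Inf, length(x))
    for (k in seq_len(nrow(centers)))
      best <- pmin(best, (x - centers[k, 1])^2 + (y - centers[k, 2])^2)
    peak * exp(-best / (2 * sig^2))
  }
}

write_fixture_files <- function(day, dir, preset) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sess_entries <- list()
  for (si in seq_along(day$sessions)) {
    s <- day$sessions[[si]]
    trk <- sprintf("%s_tracking.csv", s$session_id)
    spk <- sprintf("%s_spikes.csv", s$session_id)
    write_tracking(s$traj, file.path(dir, trk))
    named <- lapply(seq_along(s$spikes), function(k) {
      sp <- s$spikes[[k]]
      sp$unit <- list(rat = 1, day = 1, tetrode = k, cluster = 1,
                      depth_um = 100 * k)
      sp
    })
    write_spikes(named, file.path(dir, spk))
    sess_entries[[si]] <- list(session_id = s$session_id,
                               manipulation = s$manipulation,
                               platform_side = s$scene$platform_side,
                               frame_rate = s$scene$frame_rate,
                               duration = max(s$traj$t, 0),
                               tracking = trk, spikes = spk,
                               camera_correction = list(rotation = 0,
                                                        translation = c(0, 0)))
  }
  write_manifest(list(day_id = day$day_id, preset = preset, seed = day$seed,
                      sessions = sess_entries),
                 file.path(dir, "manifest.yaml"))
  gt <- lapply(day$truths, function(tr) {
    if (inherits(tr, "gf_gridtruth")) unclass(tr) else
      list(type = class(tr)[1])
  })
  yaml::write_yaml(list(note = "synthetic ground truth", truths = gt),
                   file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}
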