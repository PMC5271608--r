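#' Construct a trajectory object
#'
#' @param t time stamps, s, strictly increasing.
#' @param x,y positions, cm.
#' @param frame_rate nominal sampling rate, Hz.
#' @return `gf_trajectory` (data.frame t, x, y).
#' @export
trajectory <- function(t, x, y, frame_rate = 30) {
  if (length(t) != length(x) || length(t) != length(y))
    stop("t, x, y must have equal length")
  if (length(t) > 1 && any(diff(t) <= 0))
    stop("timestamps must be strictly increasing")
  if (any(!is.finite(c(t, x, y))))
    stop("trajectory values must be finite")
  out <- data.frame(t = t, x = x, y = y)
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("gf_trajectory", "data.frame")
  out
}

#' Construct a spike train
#'
#' @param times spike times, s (sorted internally).
#' @param unit optional list(rat, day, tetrode, cluster, depth_um).
#' @return `gf_spiketrain`.
#' @export
spike_train <- function(times, unit = NULL) {
  structure(list(times = sort(as.numeric(times)), unit = unit),
            class = "gf_spiketrain")
}

#' @export
format.gf_spiketrain <- function(x, ...) {
  id <- if (is.null(x$unit)) "unlabeled" else
    sprintf("r%sd%st%sc%s", x$unit$rat, x$unit$day, x$unit$tetrode, x$unit$cluster)
  sprintf("<spike train %s: %d spikes>", id, length(x$times))
}

#' @export
print.gf_spiketrain <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Read / write tracking files
#'
#' Plain CSV with header `t,x,y` (s, cm, cm). Round trips are lossless to
#' the written precision.
#'
#' @param path file path.
#' @param frame_rate frame rate recorded on the returned object, Hz.
#' @return [read_tracking()]: a `gf_trajectory`.
#' @export
read_tracking <- function(path, frame_rate = 30) {
  d <- utils::read.csv(path)
  if (!all(c("t", "x", "y") %in% names(d)))
    stop("tracking file must have columns t, x, y")
  if (nrow(d) > 1 && any(diff(d$t) <= 0))
    stop("tracking timestamps out of order")
  trajectory(d$t, d$x, d$y, frame_rate = frame_rate)
}

#' @rdname read_tracking
#' @param traj a `gf_trajectory`.
#' @export
write_tracking <- function(traj, path) {
  utils::write.csv(data.frame(t = traj$t, x = traj$x, y = traj$y),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write spike files
#'
#' CSV with columns rat, day, tetrode, cluster, depth_um, t; one row per
#' spike, possibly many units per file.
#'
#' @param path file path.
#' @return [read_spikes()]: list of `gf_spiketrain`, named `r<rat>d<day>t<tt>c<cl>`.
#' @export
read_spikes <- function(path) {
  d <- utils::read.csv(path)
  need <- c("rat", "day", "tetrode", "cluster", "depth_um", "t")
  if (!all(need %in% names(d))) stop("spike file must have columns ", paste(need, collapse = ", "))
  if (nrow(d) == 0) return(list())
  key <- sprintf("r%dd%dt%dc%d", d$rat, d$day, d$tetrode, d$cluster)
  out <- lapply(split(seq_len(nrow(d)), key), function(i) {
    u <- d[i[1], ]
    spike_train(d$t[i], unit = list(rat = u$rat, day = u$day, tetrode = u$tetrode,
                                    cluster = u$cluster, depth_um = u$depth_um))
  })
  out
}

#' @rdname read_spikes
#' @param spikes list of `gf_spiketrain` (each with unit metadata).
#' @export
write_spikes <- function(spikes, path) {
  rows <- lapply(spikes, function(s) {
    u <- s$unit
    if (is.null(u)) stop("spike trains need unit metadata to be written")
    if (length(s$times) == 0) return(NULL)
    data.frame(rat = u$rat, day = u$day, tetrode = u$tetrode,
               cluster = u$cluster, depth_um = u$depth_um, t = s$times)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Apply a rigid camera correction to a trajectory
#'
#' Corrections are determined upstream (the study aligned cumulative
#' trajectories between cameras by eye); here they are manifest inputs
#' applied as a rotation about the origin followed by a translation.
#'
#' @param traj `gf_trajectory`.
#' @param rotation degrees CW.
#' @param translation (dx, dy) cm.
#' @return corrected `gf_trajectory`.
#' @export
apply_camera_correction <- function(traj, rotation = 0, translation = c(0, 0)) {
  if (!all(is.finite(c(rotation, translation)))) stop("correction must be finite")
  p <- rotate_cw(traj$x, traj$y, rotation)
  out <- traj
  out$x <- p$x + translation[1]
  out$y <- p$y + translation[2]
  out
}

#' Write / read a session manifest
#'
#' YAML file describing the day's ordered sessions: id, manipulation label,
#' scene parameters, duration, camera correction, file paths. All generator
#' parameters and seeds are echoed so synthetic days are fully reproducible.
#'
#' @param manifest list as built by [run_day()]/[make_fixtures()] or by hand:
#'   `list(day_id = ..., sessions = list(list(session_id, manipulation,
#'   platform_side, duration, tracking, spikes, camera_correction = list(
#'   rotation, translation)), ...))`.
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) yaml::read_yaml(path)

#' Load a day of sessions and resolve STD references
#'
#' Reads every session in manifest order, attaches trajectories (with camera
#' corrections applied) and spike trains, and pairs each manipulated session
#' with the most recent preceding standard-configuration session (STD or
#' STD2).
#'
#' @param manifest manifest list or path to a YAML manifest.
#' @param dir directory against which relative file paths are resolved.
#' @return list with `sessions` (each: scene, traj, spikes, manipulation,
#'   std_ref index or NA) and `day_id`.
#' @export
load_day <- function(manifest, dir = ".") {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  labs <- vapply(manifest$sessions, function(s) s$manipulation, "")
  if (!any(labs %in% c("STD", "STD2")))
    stop("day has no standard-configuration session")
  sessions <- lapply(manifest$sessions, function(s) {
    scene <- scene_config(s$manipulation,
                          platform_side = s$platform_side %||% 137,
                          frame_rate = s$frame_rate %||% 30)
    traj <- read_tracking(file.path(dir, s$tracking), frame_rate = scene$frame_rate)
    cc <- s$camera_correction
    if (!is.null(cc))
      traj <- apply_camera_correction(traj, cc$rotation %||% 0,
                                      unlist(cc$translation %||% c(0, 0)))
    spikes <- if (!is.null(s$spikes)) read_spikes(file.path(dir, s$spikes)) else list()
    list(session_id = s$session_id, manipulation = s$manipulation,
         scene = scene, traj = traj, spikes = spikes)
  })
  std_like <- which(labs %in% c("STD", "STD2"))
  for (i in seq_along(sessions)) {
    prior <- std_like[std_like < i]
    sessions[[i]]$std_ref <- if (labs[i] %in% c("STD", "STD2")) NA_integer_
    else if (length(prior)) max(prior)
    else NA_integer_
  }
  manip <- which(!labs %in% c("STD", "STD2"))
  if (any(vapply(sessions[manip], function(s) is.na(s$std_ref), TRUE)))
    stop("a manipulated session precedes any standard session")
  list(day_id = manifest$day_id %||% "day", sessions = sessions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
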