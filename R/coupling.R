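# Pairwise geometric coordination of simultaneously recorded grids.

#' Measure one unit's room-frame response (rotation and phase shift)
#'
#' Convenience wrapper used by the coupling analysis: grid rotation in the
#' room frame and the phase-shift vector from the rotation-adjusted
#' crosscorrelogram.
#'
#' @param std_map,m_map smoothed maps on a common grid.
#' @param std_geom,m_geom their geometries ([grid_geometry()]); recomputed
#'   when NULL.
#' @param cfg [gf_config()].
#' @return list(rotation (deg), shift (x, y cm), std_geom, m_geom).
#' @export
unit_response <- function(std_map, m_map, std_geom = NULL, m_geom = NULL,
                          cfg = gf_config()) {
  if (is.null(std_geom)) std_geom <- grid_geometry(std_map, cfg)
  if (is.null(m_geom)) m_geom <- grid_geometry(m_map, cfg)
  if (!std_geom$ok || !m_geom$ok)
    stop("degenerate geometry: unit response requires valid grids")
  rot <- grid_rotation(std_geom, m_geom)
  shift <- phase_shift_maps(std_map, m_map, rot, cfg)
  list(rotation = rot, shift = shift, std_geom = std_geom, m_geom = m_geom)
}

#' Select grid pairs for coupling analysis
#'
#' All unordered pairs of simultaneously recorded units that pass grid
#' classification in both the STD and the manipulated session and whose STD
#' rate maps have Pearson correlation below `cfg$pair_max_corr` (grids with
#' overlapping phase/orientation are excluded so that spatial correlation is
#' comparable across same- and cross-scale pairs).
#'
#' @param units named list; each element needs `std_map`, `m_map`,
#'   `std_pass`, `m_pass` (logicals).
#' @param cfg [gf_config()].
#' @return data.frame (unit_a, unit_b, std_corr).
#' @export
select_pairs <- function(units, cfg = gf_config()) {
  nm <- names(units)
  ok <- vapply(units, function(u) isTRUE(u$std_pass) && isTRUE(u$m_pass), TRUE)
  nm <- nm[ok]
  out <- NULL
  if (length(nm) >= 2) {
    for (i in seq_len(length(nm) - 1)) for (j in (i + 1):length(nm)) {
      r <- map_correlation(units[[nm[i]]]$std_map, units[[nm[j]]]$std_map)
      if (!is.na(r) && r < cfg$pair_max_corr)
        out <- rbind(out, data.frame(unit_a = nm[i], unit_b = nm[j], std_corr = r))
    }
  }
  if (is.null(out))
    out <- data.frame(unit_a = character(0), unit_b = character(0),
                      std_corr = numeric(0))
  out
}

#' Absolute rotation difference of a grid pair
#'
#' Wrapped absolute difference of the two grids' rotations (relative to
#' their STD condition), in \[0, 30\] degrees.
#'
#' @param r1,r2 rotations, degrees (grid angular space).
#' @return degrees in \[0, 30\].
#' @export
rotation_difference <- function(r1, r2) abs(wrap_grid_angle(r1 - r2))

#' Scale-ratio class of a grid pair
#' @param scale_a,scale_b STD grid scales, cm.
#' @param breaks class boundaries (ratio), default 1.3 and 1.9.
#' @return list(scale_ratio >= 1, sr_class in "SR1","SR2","SR3").
#' @export
scale_ratio_class <- function(scale_a, scale_b, breaks = c(1.3, 1.9)) {
  sr <- max(scale_a, scale_b) / min(scale_a, scale_b)
  cls <- if (sr <= breaks[1]) "SR1" else if (sr <= breaks[2]) "SR2" else "SR3"
  list(scale_ratio = sr, sr_class = cls)
}

#' Joint correlation of a grid pair across a manipulation
#'
#' Tests whether a single rigid transform explains both grids' responses:
#' (1-2) the pair's average rotation rho (circular mean in the 60-degree
#' space) and average phase-shift vector gamma are computed from the
#' per-unit responses; (3) each of the four maps is mean-centered over its
#' occupied bins and scaled to unit norm; (4-6) the two STD maps are stacked
#' and jointly rotated by rho and shifted by gamma; (7-8) the result is the
#' cosine of the angle between the linearized stacked STD and manipulated
#' vectors, over entries defined in both.
#'
#' @param resp_a,resp_b [unit_response()] of the two units.
#' @param maps_a,maps_b lists(std_map, m_map) for the two units.
#' @return joint correlation in \[-1, 1\].
#' @export
joint_correlation <- function(resp_a, resp_b, maps_a, maps_b) {
  rho <- circ_mean_period(c(resp_a$rotation, resp_b$rotation), period = 60)
  gamma <- (resp_a$shift + resp_b$shift) / 2
  norm_map <- function(m) {
    mu <- mean(m$rate[m$occupied])
    v <- m$rate - mu
    v[!m$occupied] <- NA
    s <- sqrt(sum(v[m$occupied]^2))
    m$rate <- v / s
    m
  }
  std <- lapply(list(maps_a$std_map, maps_b$std_map),
                function(m) rigid_transform_ratemap(norm_map(m), rho, gamma))
  man <- lapply(list(maps_a$m_map, maps_b$m_map), norm_map)
  num <- 0; na2 <- 0; nb2 <- 0
  for (k in 1:2) {
    common <- std[[k]]$occupied & man[[k]]$occupied
    if (!any(common)) next
    va <- std[[k]]$rate[common]; vb <- man[[k]]$rate[common]
    num <- num + sum(va * vb)
    na2 <- na2 + sum(va^2); nb2 <- nb2 + sum(vb^2)
  }
  if (na2 == 0 || nb2 == 0) stop("degenerate geometry: no overlap after transform")
  num / sqrt(na2 * nb2)
}

#' Coupling measures for all selected pairs of one session
#'
#' @param units named list; each element needs std_map, m_map, std_pass,
#'   m_pass and (optionally precomputed) std_geom, m_geom.
#' @param cfg [gf_config()].
#' @return data.frame (unit_a, unit_b, std_corr, scale_ratio, sr_class,
#'   rotation_diff, joint_corr).
#' @export
couple_session <- function(units, cfg = gf_config()) {
  pairs <- select_pairs(units, cfg)
  if (nrow(pairs) == 0)
    return(cbind(pairs, scale_ratio = numeric(0), sr_class = character(0),
                 rotation_diff = numeric(0), joint_corr = numeric(0)))
  resp <- list()
  get_resp <- function(nm) {
    if (is.null(resp[[nm]])) {
      u <- units[[nm]]
      resp[[nm]] <<- unit_response(u$std_map, u$m_map, u$std_geom, u$m_geom, cfg)
    }
    resp[[nm]]
  }
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs$unit_a[k]; b <- pairs$unit_b[k]
    ra <- get_resp(a); rb <- get_resp(b)
    src <- scale_ratio_class(ra$std_geom$scale, rb$std_geom$scale, cfg$sr_breaks)
    jc <- joint_correlation(ra, rb, units[[a]], units[[b]])
    data.frame(unit_a = a, unit_b = b, std_corr = pairs$std_corr[k],
               scale_ratio = src$scale_ratio, sr_class = src$sr_class,
               rotation_diff = rotation_difference(ra$rotation, rb$rotation),
               joint_corr = jc)
  })
  do.call(rbind, rows)
}

#' Randomized control distributions for the coupling measures
#'
#' Each pair's alignment is perturbed `n_perturb` times: every STD map is
#' independently rotated by an angle uniform on (-30, 30) degrees, and every
#' manipulated map is shifted in a direction uniform on (-180, 180) degrees
#' by a distance uniform on (0, that grid's scale). Measurements (rotation
#' difference and joint correlation) are then re-run on the perturbed maps
#' through the same field-detection pipeline.
#'
#' @param units named list as in [couple_session()].
#' @param pairs pair table from [couple_session()] / [select_pairs()].
#' @param n_perturb perturbations per pair.
#' @param seed integer seed.
#' @param cfg [gf_config()].
#' @return data.frame (unit_a, unit_b, replicate, rotation_diff, joint_corr;
#'   NA where the perturbed maps lost measurable grid structure).
#' @export
control_distributions <- function(units, pairs, n_perturb = 10, seed = 1,
                                  cfg = gf_config()) {
  if (nrow(pairs) == 0)
    return(data.frame(unit_a = character(0), unit_b = character(0),
                      replicate = integer(0), rotation_diff = numeric(0),
                      joint_corr = numeric(0)))
  with_seed(seed, {
    rows <- list()
    for (k in seq_len(nrow(pairs))) {
      a <- pairs$unit_a[k]; b <- pairs$unit_b[k]
      for (rep_i in seq_len(n_perturb)) {
        pert <- lapply(units[c(a, b)], function(u) {
          scale_u <- if (!is.null(u$std_geom)) u$std_geom$scale else
            grid_geometry(u$std_map, cfg)$scale
          ang <- stats::runif(1, -30, 30)
          d_dir <- stats::runif(1, -180, 180)
          d_len <- stats::runif(1, 0, scale_u)
          list(std_map = rotate_ratemap(u$std_map, ang),
               m_map = translate_ratemap(u$m_map, d_len * dir_cw(d_dir)))
        })
        meas <- tryCatch({
          ra <- unit_response(pert[[1]]$std_map, pert[[1]]$m_map, cfg = cfg)
          rb <- unit_response(pert[[2]]$std_map, pert[[2]]$m_map, cfg = cfg)
          jc <- joint_correlation(ra, rb, pert[[1]], pert[[2]])
          c(rotation_difference(ra$rotation, rb$rotation), jc)
        }, error = function(e) c(NA_real_, NA_real_))
        rows[[length(rows) + 1]] <-
          data.frame(unit_a = a, unit_b = b, replicate = rep_i,
                     rotation_diff = meas[1], joint_corr = meas[2])
      }
    }
    do.call(rbind, rows)
  })
}
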