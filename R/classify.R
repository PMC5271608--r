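#' Elliptical correction of a rate map
#'
#' If the autocorrelogram's elliptical index exceeds `threshold`, the rate
#' map is stretched along the direction of the ellipse's shorter axis by
#' A/B, so the corrected autocorrelogram's inner fields lie on a near-circle;
#' fields and geometry must be recomputed on the result. Below the
#' threshold the map is returned unchanged.
#'
#' @param map smoothed `gf_ratemap`.
#' @param geom [grid_geometry()] of `map`.
#' @param threshold elliptical-index threshold for applying the correction.
#' @return `gf_ratemap` with attribute `corrected` (logical).
#' @export
elliptical_correction <- function(map, geom, threshold = 0.05) {
  if (!geom$ok || is.null(geom$ellipse) || geom$ellipse$index <= threshold) {
    attr(map, "corrected") <- FALSE
    return(map)
  }
  out <- stretch_ratemap(map, factor = geom$ellipse$A / geom$ellipse$B,
                         axis_angle = geom$ellipse$minor_angle)
  attr(out, "corrected") <- TRUE
  out
}

#' Gridness score of a rate map
#'
#' After elliptical correction (if the elliptical index is > 0.05, with
#' geometry recomputed from the corrected map), the autocorrelogram annulus
#' containing the six inner vertices is isolated: inner/outer radii
#' D -/+ 1.2 cR, where D is the mean vertex distance and cR the radius of
#' the circle with the central field's area. Pearson correlations between
#' the annulus and rotated copies of itself are taken at 30-degree steps;
#' the score is min(r(60), r(120)) - max(r(30), r(90), r(150)) (offset sets
#' configurable). Six-fold-symmetric maps score high; square lattices score
#' negative; rotationally symmetric maps score near 0.
#'
#' @param map smoothed `gf_ratemap`.
#' @param cfg [gf_config()].
#' @param geom optional precomputed [grid_geometry()] of `map`.
#' @return list(score, ok, reason, corrected, geom (pre-correction),
#'   geom_used (post-correction), rotation_r (named correlations)).
#' @export
gridness_score <- function(map, cfg = gf_config(), geom = NULL) {
  if (is.null(geom)) geom <- grid_geometry(map, cfg)
  fail <- function(reason) list(score = NA_real_, ok = FALSE, reason = reason,
                                corrected = FALSE, geom = geom, geom_used = geom,
                                rotation_r = NULL)
  if (!geom$ok) return(fail(geom$reason))
  corrected <- geom$ellipse$index > cfg$ellipse_correct_thresh
  if (corrected) {
    map2 <- elliptical_correction(map, geom, cfg$ellipse_correct_thresh)
    geom2 <- grid_geometry(map2, cfg)
    if (!geom2$ok) return(fail(paste("after correction:", geom2$reason)))
  } else geom2 <- geom
  acorr <- geom2$acorr
  fields <- geom2$fields
  vert <- fields[match(geom2$ellipse$vertex_idx, fields$field), ]
  D <- mean(vert$dist)
  cR <- sqrt(fields$area[fields$central][1] / pi) * acorr$bin_size
  rin <- max(D - cfg$annulus_width_factor * cR, 0)
  rout <- D + cfg$annulus_width_factor * cR
  dxc <- acorr$dx * acorr$bin_size
  dyc <- acorr$dy * acorr$bin_size
  dxm <- matrix(dxc, length(dxc), length(dyc))
  dym <- matrix(dyc, length(dxc), length(dyc), byrow = TRUE)
  rad <- sqrt(dxm^2 + dym^2)
  ann <- rad >= rin & rad <= rout & acorr$valid & !is.na(acorr$r)
  if (sum(ann) < 2) return(fail("annulus not constructible"))
  offsets <- sort(unique(c(cfg$gridness_peak_offsets, cfg$gridness_trough_offsets)))
  rot_r <- vapply(offsets, function(off) {
    src <- rotate_cw(dxm[ann], dym[ann], -off)
    rotv <- bilinear_sample(acorr$r, acorr$valid, dxc, dyc, src$x, src$y)
    ok <- !is.na(rotv)
    if (sum(ok) < 2) return(NA_real_)
    stats::cor(acorr$r[ann][ok], rotv[ok])
  }, 0)
  names(rot_r) <- offsets
  peaks <- rot_r[as.character(cfg$gridness_peak_offsets)]
  troughs <- rot_r[as.character(cfg$gridness_trough_offsets)]
  if (any(is.na(c(peaks, troughs)))) return(fail("rotation correlations undefined"))
  list(score = min(peaks) - max(troughs), ok = TRUE, reason = NULL,
       corrected = corrected, geom = geom, geom_used = geom2, rotation_r = rot_r)
}

#' Seven-criterion bootstrap grid-cell classification
#'
#' A rate map is classified as produced by a grid cell when all of:
#' gridness >= 0.1; the six annulus-defining correlation fields are
#' identified; the angles subtended by adjacent canonical semi-axes are
#' > 30 and < 90 degrees (exclusive); elliptical index < 0.5; no vertex
#' field lies farther from the fitted ellipse than 20% of its distance from
#' the autocorrelogram center; grid scale < 125 cm; and gridness >= 0.1 in
#' at least 95 of 100 bootstrapped rate maps. Criteria that cannot be
#' evaluated after an earlier failure are reported as NA.
#'
#' @param map smoothed `gf_ratemap`.
#' @param bootstraps list of bootstrapped smoothed maps (see
#'   [bootstrap_rate_maps()]), or NULL to leave the bootstrap criterion
#'   unevaluated (it is skipped anyway when an earlier criterion fails).
#' @param cfg [gf_config()].
#' @return `gf_classification`: list(criteria (named logical, NA = not
#'   evaluated), pass, gridness, bootstrap_pass_count, geom, score).
#' @export
classify_grid <- function(map, bootstraps = NULL, cfg = gf_config()) {
  gs <- gridness_score(map, cfg)
  crit <- c(gridness = NA, six_fields = NA, axis_angles = NA, elliptical = NA,
            ellipse_distance = NA, scale = NA, bootstrap = NA)
  geom <- gs$geom
  crit["six_fields"] <- gs$ok
  if (gs$ok) {
    crit["gridness"] <- gs$score >= cfg$gridness_thresh
    ax <- geom$axes
    sep <- c((ax$ax0 - ax$ax1) %% 360, (ax$ax2 - ax$ax0) %% 360)
    crit["axis_angles"] <- all(sep > 30 & sep < 90)
    crit["elliptical"] <- geom$ellipse$index < cfg$ellipse_reject_thresh
    fr <- ellipse_distance_fractions(geom$fields, geom$ellipse)
    crit["ellipse_distance"] <- all(fr <= cfg$ellipse_dist_frac)
    crit["scale"] <- geom$scale < cfg$max_scale
  }
  early_ok <- all(crit[1:6] %in% TRUE)
  npass <- NA_integer_
  if (early_ok && !is.null(bootstraps)) {
    scores <- vapply(bootstraps, function(b) {
      s <- gridness_score(b, cfg)
      if (s$ok) s$score else -Inf
    }, 0)
    npass <- sum(scores >= cfg$gridness_thresh)
    crit["bootstrap"] <- npass >= cfg$bootstrap_pass
  }
  structure(list(criteria = crit, pass = isTRUE(all(crit %in% TRUE)),
                 gridness = gs$score, bootstrap_pass_count = npass,
                 geom = geom, score_detail = gs),
            class = "gf_classification")
}

#' @export
print.gf_classification <- function(x, ...) {
  cat(sprintf("<grid classification: %s (gridness %.2f)>\n",
              if (x$pass) "PASS" else "fail", x$gridness))
  print(x$criteria)
  invisible(x)
}

#' Classify one session's unit end to end
#'
#' Builds the smoothed rate map from raw trajectory and spikes, evaluates
#' the first six criteria, and only then generates and scores the bootstrap
#' replicates (a map failing earlier criteria cannot pass regardless).
#'
#' @param traj `gf_trajectory` (unfiltered).
#' @param spikes `gf_spiketrain`.
#' @param cfg [gf_config()].
#' @param extent map extent (see [map_extent()]).
#' @param seed seed for the bootstrap resampling.
#' @return list(map, classification).
#' @export
classify_session <- function(traj, spikes, cfg = gf_config(), extent = NULL,
                             seed = 1) {
  map <- rate_map_pipeline(traj, spikes, cfg, extent)
  cl <- classify_grid(map, bootstraps = NULL, cfg = cfg)
  if (all(cl$criteria[1:6] %in% TRUE) && length(spikes$times) > 0) {
    bs <- bootstrap_rate_maps(traj, spikes, cfg$n_bootstrap, seed, cfg, extent)
    cl <- classify_grid(map, bootstraps = bs, cfg = cfg)
  }
  list(map = map, classification = cl)
}
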