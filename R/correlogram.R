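#' Spatial crosscorrelogram of two rate maps
#'
#' Map of Pearson correlations between `mapA` and `mapB` for every discrete
#' displacement of the first map relative to the second. The correlation at
#' displacement (dx, dy) is computed over the bins occupied in both maps
#' after displacing `mapB` by (-dx, -dy); displacements whose overlap
#' contains fewer than `min_overlap` co-occupied bins are marked invalid.
#' A correlation-field peak at displacement d therefore means the pattern of
#' `mapB` is offset by +d relative to `mapA`.
#'
#' @param mapA,mapB `gf_ratemap`s with equal bin size.
#' @param min_overlap minimum co-occupied bins per displacement.
#' @return `gf_correlogram`: list(r, valid, n, dx, dy, bin_size) with `dx`,
#'   `dy` displacement vectors in bins.
#' @export
crosscorrelogram <- function(mapA, mapB, min_overlap = 100) {
  if (abs(mapA$bin_size - mapB$bin_size) > 1e-9)
    stop("bin sizes differ between maps")
  A <- mapA$rate; A[!mapA$occupied] <- NA
  B <- mapB$rate; B[!mapB$occupied] <- NA
  s <- masked_xcorr_sums(A, B)
  n <- s$n
  vx <- pmax(n * s$saa - s$sa^2, 0)
  vy <- pmax(n * s$sbb - s$sb^2, 0)
  denom <- sqrt(vx * vy)
  r <- (n * s$sab - s$sa * s$sb) / denom
  tol <- 1e-8 * pmax(n, 1)
  valid <- n >= min_overlap & vx > tol & vy > tol
  r[!valid] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  structure(list(r = r, valid = valid, n = n, dx = s$dx, dy = s$dy,
                 bin_size = mapA$bin_size), class = "gf_correlogram")
}

#' Spatial autocorrelogram of a rate map
#'
#' [crosscorrelogram()] of a map with itself, symmetrized under point
#' reflection (exact in theory; enforced against floating-point noise).
#'
#' @param map `gf_ratemap`.
#' @param min_overlap minimum co-occupied bins per displacement.
#' @return `gf_correlogram`.
#' @export
autocorrelogram <- function(map, min_overlap = 100) {
  cg <- crosscorrelogram(map, map, min_overlap)
  rev2 <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
  cg$valid <- cg$valid & rev2(cg$valid)
  r2 <- (cg$r + rev2(cg$r)) / 2
  r2[!cg$valid] <- NA_real_
  cg$r <- r2
  cg
}

#' Detect correlation fields in a correlogram
#'
#' Connected regions (8-connectivity) of at least `min_bins` bins with
#' correlation uniformly above `r_thresh`. Each field's center of mass is
#' computed over the field's core — the bins at or above the midpoint
#' between the threshold and the field's peak correlation — weighted by the
#' correlation excess over the threshold. Centering on the core keeps the
#' estimate insensitive to how far the field's low-correlation skirt happens
#' to stay above threshold (which depends on overlap size and neighboring
#' correlogram structure), and the excess weighting makes it continuous as
#' boundary bins enter or leave the component; the field's `area` still
#' counts every component bin.
#'
#' @param corr `gf_correlogram`.
#' @param r_thresh correlation threshold.
#' @param min_bins minimum contiguous bins per field.
#' @return data.frame (field, com_x, com_y (cm), area (bins), dist (cm),
#'   central flag), ordered by distance from the correlogram center. The
#'   central field is the one nearest (0, 0) (ties to the larger area).
#' @export
detect_fields <- function(corr, r_thresh = 0.1, min_bins = 20) {
  mask <- corr$valid & !is.na(corr$r) & corr$r > r_thresh
  lab <- label_components(mask, connectivity = 8)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  empty <- data.frame(field = integer(0), com_x = numeric(0), com_y = numeric(0),
                      area = integer(0), dist = numeric(0), central = logical(0))
  if (!length(ids)) return(empty)
  dxm <- matrix(corr$dx, length(corr$dx), length(corr$dy))
  dym <- matrix(corr$dy, length(corr$dx), length(corr$dy), byrow = TRUE)
  rows <- lapply(ids, function(id) {
    sel <- lab == id
    area <- sum(sel)
    if (area < min_bins) return(NULL)
    half <- (max(corr$r[sel]) + r_thresh) / 2
    core <- sel & corr$r >= half
    w <- corr$r[core] - r_thresh
    data.frame(com_x = sum(w * dxm[core]) / sum(w) * corr$bin_size,
               com_y = sum(w * dym[core]) / sum(w) * corr$bin_size,
               area = area)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out$dist <- sqrt(out$com_x^2 + out$com_y^2)
  out <- out[order(out$dist, -out$area), , drop = FALSE]
  out$central <- FALSE
  out$central[1] <- TRUE
  out <- cbind(field = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Canonical grid axes from correlation fields
#'
#' Among the six fields closest to the center (excluding the central field),
#' AX0 is the semi-axis direction closest to the positive x axis (the exact
#' +/-30 degree tie resolved to the CCW candidate), AX1 the first semi-axis
#' CCW of AX0, AX2 the first CW. Grid orientation is their circular mean in
#' the 60-degree-periodic axis space.
#'
#' @param fields output of [detect_fields()] on an autocorrelogram.
#' @return list(ax0, ax1, ax2 (deg CW), orientation (deg, \[-30, 30)),
#'   field_idx (rows of `fields` defining the axes), vertex_idx (the six
#'   inner fields)).
#' @export
canonical_axes <- function(fields) {
  nc <- fields[!fields$central, , drop = FALSE]
  if (nrow(nc) < 3) stop("degenerate geometry: fewer than 3 non-central fields")
  nc <- nc[order(nc$dist), , drop = FALSE]
  vert <- utils::head(nc, 6)
  ang <- vector_angle_cw(vert$com_x, vert$com_y)
  score <- abs(ang) + ifelse(abs(abs(ang) - 30) < 1e-9 & ang > 0, 1e-6, 0)
  i0 <- which.min(score)
  a0 <- ang[i0]
  rel_ccw <- (a0 - ang) %% 360   # positive = CCW of ax0
  rel_cw <- (ang - a0) %% 360
  rel_ccw[i0] <- Inf; rel_cw[i0] <- Inf
  i1 <- which.min(rel_ccw)
  i2 <- which.min(rel_cw)
  if (i1 == i2) stop("degenerate geometry: axes not separable")
  orientation <- circ_mean_period(c(a0, ang[i1], ang[i2]), period = 60)
  list(ax0 = a0, ax1 = ang[i1], ax2 = ang[i2], orientation = orientation,
       field_idx = vert$field[c(i0, i1, i2)], vertex_idx = vert$field)
}

#' Grid scale from the canonical-axis fields
#'
#' Mean distance (cm) of the three correlation fields defining the canonical
#' axes from the center of the autocorrelogram.
#'
#' @param fields output of [detect_fields()].
#' @param axes output of [canonical_axes()].
#' @return scale, cm.
#' @export
grid_scale <- function(fields, axes) {
  mean(fields$dist[match(axes$field_idx, fields$field)])
}

# Direct least-squares (conic) ellipse fit; returns semi-axes a >= b, the
# major-axis direction in degrees CW, and the center.
fit_ellipse <- function(x, y) {
  if (length(x) < 5) stop("ellipse fit needs >= 5 points")
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) - Re(ev$vectors[2, ])^2
  k <- which(cond > 0)
  if (!length(k)) stop("degenerate geometry: no ellipse solution")
  a1 <- Re(ev$vectors[, k[1]])
  coefs <- c(a1, as.vector(Tm %*% a1))   # A B C D E F
  if (coefs[1] + coefs[3] < 0) coefs <- -coefs   # positive-definite form
  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  D <- coefs[4]; E <- coefs[5]; F <- coefs[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - B * D * E - 4 * A * C * F)
  disc <- sqrt((A - C)^2 + B^2)
  ax1 <- -sqrt(abs(num * (A + C + disc))) / den
  ax2 <- -sqrt(abs(num * (A + C - disc))) / den
  semi <- sort(c(ax1, ax2), decreasing = TRUE)
  theta_ccw <- atan2(C - A - disc, B)    # major axis, CCW from +x
  wrap_axis <- function(a) ((a + 90) %% 180) - 90   # axis directions are mod 180
  list(a = semi[1], b = semi[2],
       major_angle = wrap_axis(-theta_ccw * 180 / pi),
       center = c(cx, cy))
}

#' Elliptical index of a grid's inner correlation fields
#'
#' Direct least-squares ellipse fit to the centers of mass of the six fields
#' most closely surrounding the central field; index = 1 - B/A (0 for a
#' perfect circle).
#'
#' @param fields output of [detect_fields()] on an autocorrelogram.
#' @return list(A, B (cm), index, major_angle, minor_angle (deg CW), center,
#'   vertex_idx).
#' @export
fit_ellipse_index <- function(fields) {
  nc <- fields[!fields$central, , drop = FALSE]
  if (nrow(nc) < 6) stop("degenerate geometry: fewer than 6 surrounding fields")
  nc <- nc[order(nc$dist), , drop = FALSE][1:6, ]
  e <- fit_ellipse(nc$com_x, nc$com_y)
  list(A = e$a, B = e$b, index = 1 - e$b / e$a,
       major_angle = e$major_angle,
       minor_angle = ((e$major_angle + 90 + 90) %% 180) - 90,
       center = e$center, vertex_idx = nc$field)
}

# radial distance of each of the six vertex fields from the fitted ellipse,
# as a fraction of the field's distance from the correlogram center
ellipse_distance_fractions <- function(fields, ell) {
  v <- fields[match(ell$vertex_idx, fields$field), ]
  qx <- v$com_x - ell$center[1]; qy <- v$com_y - ell$center[2]
  psi <- (-atan2(qy, qx)) - ell$major_angle * pi / 180   # CW angle from major axis
  re <- ell$A * ell$B / sqrt((ell$B * cos(psi))^2 + (ell$A * sin(psi))^2)
  abs(sqrt(qx^2 + qy^2) - re) / v$dist
}

#' Grid geometry of one rate map
#'
#' Autocorrelogram, correlation fields, canonical axes, orientation, scale
#' and elliptical index. Returns a degenerate result (with `ok = FALSE` and
#' a reason) rather than an error when the map has no usable grid structure.
#'
#' @param map smoothed `gf_ratemap`.
#' @param cfg [gf_config()].
#' @return object of class `gf_gridgeom`.
#' @export
grid_geometry <- function(map, cfg = gf_config()) {
  acorr <- autocorrelogram(map, cfg$min_overlap)
  fields <- detect_fields(acorr, cfg$field_r_thresh, cfg$field_min_bins)
  out <- structure(list(ok = FALSE, reason = NULL, acorr = acorr,
                        fields = fields, axes = NULL, orientation = NA_real_,
                        scale = NA_real_, ellipse = NULL, n_fields = nrow(fields)),
                   class = "gf_gridgeom")
  if (nrow(fields) < 7) {
    out$reason <- "fewer than 6 surrounding correlation fields"
    return(out)
  }
  axes <- tryCatch(canonical_axes(fields), error = function(e) NULL)
  if (is.null(axes)) { out$reason <- "canonical axes not found"; return(out) }
  ell <- tryCatch(fit_ellipse_index(fields), error = function(e) NULL)
  if (is.null(ell)) { out$reason <- "ellipse fit failed"; return(out) }
  out$axes <- axes
  out$orientation <- axes$orientation
  out$scale <- grid_scale(fields, axes)
  out$ellipse <- ell
  out$ok <- TRUE
  out
}

#' @export
print.gf_gridgeom <- function(x, ...) {
  if (x$ok)
    cat(sprintf("<grid geometry: orientation %.1f deg, scale %.1f cm, elliptical index %.3f, %d fields>\n",
                x$orientation, x$scale, x$ellipse$index, x$n_fields))
  else cat(sprintf("<grid geometry: degenerate (%s)>\n", x$reason))
  invisible(x)
}
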