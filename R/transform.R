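# Geometric transforms of rate maps. All resample the input on its own bin
# grid with NA-aware bilinear interpolation (invalid neighbors dropped and
# weights renormalized; a bin stays defined only if at least half the
# bilinear mass is valid).

resample_ratemap <- function(map, inverse_fn, min_weight = 0.5) {
  g <- expand.grid(x = map$x, y = map$y)
  src <- inverse_fn(g$x, g$y)
  v <- bilinear_sample(map$rate, map$occupied, map$x, map$y, src$x, src$y,
                       min_weight = min_weight)
  out <- map
  out$rate <- matrix(v, length(map$x), length(map$y))
  out$occupied <- !is.na(out$rate)
  out
}

#' Rotate a rate map about a point
#' @param map `gf_ratemap`.
#' @param theta rotation, degrees CW.
#' @param center rotation center (x, y), cm.
#' @return rotated `gf_ratemap` on the same grid.
#' @export
rotate_ratemap <- function(map, theta, center = c(0, 0)) {
  resample_ratemap(map, function(x, y) {
    p <- rotate_cw(x - center[1], y - center[2], -theta)
    list(x = p$x + center[1], y = p$y + center[2])
  })
}

#' Translate a rate map
#' @param map `gf_ratemap`.
#' @param shift (dx, dy), cm.
#' @return translated `gf_ratemap` on the same grid.
#' @export
translate_ratemap <- function(map, shift) {
  resample_ratemap(map, function(x, y) list(x = x - shift[1], y = y - shift[2]))
}

#' Stretch a rate map along an axis
#'
#' Rescales the image by `factor` along the direction `axis_angle` (degrees
#' CW from +x), about the map origin; used for elliptical correction.
#'
#' @param map `gf_ratemap`.
#' @param factor stretch factor (> 1 expands along the axis).
#' @param axis_angle stretch axis, degrees CW.
#' @return stretched `gf_ratemap` on the same grid.
#' @export
stretch_ratemap <- function(map, factor, axis_angle) {
  u <- dir_cw(axis_angle)
  resample_ratemap(map, function(x, y) {
    proj <- x * u[1] + y * u[2]
    k <- 1 / factor - 1
    list(x = x + k * proj * u[1], y = y + k * proj * u[2])
  })
}

#' Rigid transform (rotation about origin, then translation) of a rate map
#' @param map `gf_ratemap`.
#' @param theta degrees CW.
#' @param shift (dx, dy), cm.
#' @return transformed `gf_ratemap`.
#' @export
rigid_transform_ratemap <- function(map, theta, shift = c(0, 0)) {
  resample_ratemap(map, function(x, y) {
    rotate_cw(x - shift[1], y - shift[2], -theta)
  })
}
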