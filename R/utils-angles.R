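#' Angle conventions
#'
#' All angles in this package are in degrees and clockwise-positive, matching
#' the reporting convention of cue-control experiments (a platform rotated
#' "20 degrees CW" has angle +20). With y pointing up, rotating the vector
#' (x, y) by a clockwise angle `theta` gives
#' `(x cos t + y sin t, -x sin t + y cos t)`.
#'
#' @name angle-conventions
#' @keywords internal
NULL

#' Wrap angles into \[-180, 180)
#' @param a angle(s), degrees.
#' @return wrapped angle(s).
#' @keywords internal
wrap_pm180 <- function(a) ((a + 180) %% 360) - 180

#' Wrap angles into the 60-degree-symmetric grid range \[-30, 30)
#'
#' Because of its hexagonal symmetry, a grid rotation is only defined modulo
#' 60 degrees; the circular range \[-30, +30) (with -30 identified with +30)
#' is the canonical representative.
#'
#' @param a angle(s), degrees (clockwise positive).
#' @return angle(s) in \[-30, 30).
#' @export
#' @examples
#' wrap_grid_angle(70)   # +10
#' wrap_grid_angle(-45)  # +15
wrap_grid_angle <- function(a) ((a + 30) %% 60) - 30

#' Clockwise angle of a 2-D vector from the +x axis
#' @param dx,dy vector components (cm or bins).
#' @return angle in degrees, clockwise positive, in \[-180, 180).
#' @keywords internal
vector_angle_cw <- function(dx, dy) wrap_pm180(-atan2(dy, dx) * 180 / pi)

#' Rotate 2-D points clockwise
#' @param x,y coordinates.
#' @param theta clockwise rotation, degrees.
#' @return list with rotated `x`, `y`.
#' @keywords internal
rotate_cw <- function(x, y, theta) {
  t <- theta * pi / 180
  list(x = x * cos(t) + y * sin(t), y = -x * sin(t) + y * cos(t))
}

#' Circular mean of angles with a given period
#'
#' Angles are mapped to the unit circle after scaling the period to 360
#' degrees, averaged as unit vectors, and mapped back.
#'
#' @param a angles, degrees.
#' @param period periodicity in degrees (360 for plain angles, 60 for grid
#'   axes/rotations).
#' @return mean angle in \[-period/2, period/2).
#' @keywords internal
circ_mean_period <- function(a, period = 360) {
  phi <- a * (2 * pi / period)
  m <- atan2(mean(sin(phi)), mean(cos(phi)))
  v <- m * period / (2 * pi)
  ((v + period / 2) %% period) - period / 2
}

#' Run an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so internal randomness does not disturb
#' the caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Derive a reproducible child seed from a master seed and a label
#'
#' Stable string hash (djb2-style, kept below 2^31) so that per-stage,
#' per-unit seeds are decorrelated but fully determined by the master seed.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the stage/unit.
#' @return integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master, ...) {
  lab <- paste(c(master, ...), collapse = "/")
  h <- 5381
  for (k in utf8ToInt(lab)) h <- (h * 33 + k) %% 2147483629
  as.integer(h %% 2147483645 + 1)
}
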