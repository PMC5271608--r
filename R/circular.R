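# 60-degree-symmetric circular statistics. Grid rotations live on a
# [-30, +30) circle; tests are run after linear expansion (x6) onto the full
# [-180, 180) circle, and descriptive values are mapped back (/6).

#' Expand grid-range angles onto the full circle
#'
#' Multiplies angles in \[-30, 30) by 6, mapping the grid's circular range
#' linearly onto \[-180, 180). Test statistics are computed in the expanded
#' space; descriptive statistics are contracted back with
#' [contract_angles()].
#'
#' @param a angles, degrees, in \[-30, 30).
#' @return expanded angles in \[-180, 180).
#' @export
expand_angles <- function(a) {
  if (any(a < -30 | a >= 30)) stop("angles must lie in [-30, 30)")
  a * 6
}

#' @rdname expand_angles
#' @param e expanded angles, degrees.
#' @export
contract_angles <- function(e) wrap_grid_angle(e / 6)

#' Mean vector of a grid-rotation sample
#'
#' Resultant of unit vectors in the expanded (x6) space; the mean direction
#' is mapped back to the \[-30, 30) range. The vector length (in \[0, 1\])
#' is a measure of circular concentration.
#'
#' @param a angles, degrees, in \[-30, 30).
#' @return list(direction (deg, \[-30, 30)), length).
#' @export
mean_vector <- function(a) {
  if (!length(a)) stop("empty sample")
  phi <- expand_angles(a) * pi / 180
  C <- mean(cos(phi)); S <- mean(sin(phi))
  list(direction = contract_angles(atan2(S, C) * 180 / pi),
       length = sqrt(C^2 + S^2))
}

# memoized Monte Carlo null sample of the Rao spacing statistic
.rao_cache <- new.env(parent = emptyenv())

rao_statistic <- function(deg360) {
  n <- length(deg360)
  s <- sort(deg360 %% 360)
  sp <- c(diff(s), 360 - s[n] + s[1])
  0.5 * sum(abs(sp - 360 / n))
}

rao_null <- function(n, nsim = 10000) {
  key <- sprintf("n%d_%d", n, nsim)
  if (!is.null(.rao_cache[[key]])) return(.rao_cache[[key]])
  stats <- with_seed(derive_seed(271828, "rao-null", n, nsim), {
    m <- matrix(stats::runif(nsim * n, 0, 360), nsim, n)
    m <- t(apply(m, 1, sort))
    sp <- cbind(m[, -1, drop = FALSE] - m[, -n, drop = FALSE],
                360 - m[, n] + m[, 1])
    0.5 * rowSums(abs(sp - 360 / n))
  })
  .rao_cache[[key]] <- stats
  stats
}

#' Rao's spacing test for circular uniformity
#'
#' Tests whether a sample of grid rotations is significantly clustered.
#' Angles are expanded onto the full circle before testing. The null
#' distribution of the spacing statistic U = 1/2 sum|T_i - 360/n| is
#' simulated (memoized Monte Carlo under uniformity, fixed internal seed,
#' `nsim` draws), which reproduces the published critical-value tables
#' without transcribing a particular edition; the p value is the upper-tail
#' proportion with the +1 continuity correction. Requires n > 7.
#'
#' @param a angles, degrees, in \[-30, 30) (or expanded degrees with
#'   `expanded = TRUE`).
#' @param expanded set TRUE if `a` is already on the full circle.
#' @param nsim Monte Carlo null size.
#' @return list(statistic (deg), p.value, level (one of "n.s.", "p<0.05",
#'   "p<0.01", "p<0.001"), n).
#' @export
rao_spacing_test <- function(a, expanded = FALSE, nsim = 10000) {
  n <- length(a)
  if (n <= 7) stop("Rao spacing test requires n > 7")
  deg <- if (expanded) a else expand_angles(a)
  U <- rao_statistic(deg)
  null <- rao_null(n, nsim)
  p <- (1 + sum(null >= U)) / (length(null) + 1)
  level <- if (p < 0.001) "p<0.001" else if (p < 0.01) "p<0.01"
           else if (p < 0.05) "p<0.05" else "n.s."
  list(statistic = U, p.value = p, level = level, n = n)
}

# half-width (degrees) of the mean-direction confidence interval at level
# 1 - alpha (Zar's formulation); NA when the sample is too dispersed for the
# interval to exist
circ_ci_halfwidth <- function(n, rbar, alpha) {
  R <- n * rbar
  chi <- stats::qchisq(1 - alpha, df = 1)
  if (rbar < 0.9) {
    num <- 2 * n * (2 * R^2 - n * chi)
    if (num <= 0) return(NA_real_)
    arg <- sqrt(num / (4 * n - chi)) / R
  } else {
    inner <- n^2 - (n^2 - R^2) * exp(chi / n)
    if (inner <= 0) return(NA_real_)
    arg <- sqrt(inner) / R
  }
  if (arg > 1) return(NA_real_)
  acos(arg) * 180 / pi
}

#' Confidence-interval test of a mean grid angle against a hypothesis
#'
#' Builds the 95, 99, 99.9 and 99.99% confidence intervals around the
#' sample's mean direction (in expanded space) and reports the p level of
#' the largest interval that excludes the hypothesized angle ("n.s." when
#' the hypothesis falls inside the 95% interval, or when the sample is too
#' dispersed for an interval to exist). Requires n > 7.
#'
#' @param a angles, degrees, in \[-30, 30).
#' @param hypothesized hypothesized angle, degrees, in \[-30, 30).
#' @return list(level in c("n.s.","p<0.05","p<0.01","p<0.001","p<0.0001"),
#'   mean, n, offsets (named half-widths, deg, expanded space)).
#' @export
ci_test_vs_angle <- function(a, hypothesized) {
  n <- length(a)
  if (n <= 7) stop("confidence-interval test requires n > 7")
  mv <- mean_vector(a)
  mu_e <- expand_angles(mv$direction)
  hyp_e <- expand_angles(wrap_grid_angle(hypothesized))
  dist <- abs(wrap_pm180(mu_e - hyp_e))
  alphas <- c("p<0.05" = 0.05, "p<0.01" = 0.01, "p<0.001" = 0.001,
              "p<0.0001" = 0.0001)
  hw <- vapply(alphas, function(al) circ_ci_halfwidth(n, mv$length, al), 0)
  excl <- !is.na(hw) & dist > hw
  level <- if (any(excl)) names(alphas)[max(which(excl))] else "n.s."
  list(level = level, mean = mv$direction, n = n, offsets = hw)
}

#' Thin a unit set of putative across-day duplicates
#'
#' Enforces, separately for each manipulation type, that no two retained
#' units recorded from the same tetrode on different days lie within
#' `min_distance` of estimated anatomical depth. Conflicts are resolved
#' deterministically: units are scanned by (day, cluster) order and a unit
#' is dropped if a retained earlier unit from the same tetrode on another
#' day is closer than `min_distance`. A unit discarded for one manipulation
#' may be retained for another; units with missing depth are excluded with
#' a warning. Thinning an already-thinned set changes nothing.
#'
#' @param units data.frame with columns rat, day, tetrode, cluster,
#'   depth_um, manipulation.
#' @param min_distance um.
#' @return the retained subset of `units` (row order preserved).
#' @export
thin_units <- function(units, min_distance = 150) {
  need <- c("rat", "day", "tetrode", "cluster", "depth_um", "manipulation")
  if (!all(need %in% names(units)))
    stop("units must have columns ", paste(need, collapse = ", "))
  if (anyNA(units$depth_um)) {
    warning(sum(is.na(units$depth_um)), " unit(s) without depth excluded from thinning")
    units <- units[!is.na(units$depth_um), , drop = FALSE]
  }
  keep <- rep(TRUE, nrow(units))
  grp <- interaction(units$rat, units$tetrode, units$manipulation, drop = TRUE)
  for (g in levels(grp)) {
    rows <- which(grp == g)
    rows <- rows[order(units$day[rows], units$cluster[rows])]
    kept <- integer(0)
    for (r in rows) {
      conflict <- any(units$day[kept] != units$day[r] &
                        abs(units$depth_um[kept] - units$depth_um[r]) < min_distance)
      if (conflict) keep[r] <- FALSE else kept <- c(kept, r)
    }
  }
  units[keep, , drop = FALSE]
}
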