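# Matrix convention used throughout: m[i, j] holds the value of the bin whose
# center is (xc[i], yc[j]); rows index x (rightward), columns index y (upward).

#' Label connected components of a binary matrix
#'
#' Iterative minimum-label propagation; NA treated as background.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8: diagonal neighbors are contiguous).
#' @return integer matrix; 0 = background, components numbered 1..k by first
#'   (column-major) occurrence.
#' @keywords internal
label_components <- function(mask, connectivity = 8) {
  mask[is.na(mask)] <- FALSE
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  # two-pass union-find over masked pixels in column-major scan order
  parent <- integer(0)
  find <- function(a) {
    while (parent[a] != a) { parent[a] <- parent[parent[a]]; a <- parent[a] }
    a
  }
  nlab <- 0L
  for (p in idx) {
    i <- (p - 1L) %% nr + 1L
    j <- (p - 1L) %/% nr + 1L
    nb <- integer(0)
    if (i > 1L && lab[p - 1L] > 0L) nb <- c(nb, lab[p - 1L])
    if (j > 1L) {
      q <- p - nr
      if (lab[q] > 0L) nb <- c(nb, lab[q])
      if (connectivity == 8) {
        if (i > 1L && lab[q - 1L] > 0L) nb <- c(nb, lab[q - 1L])
        if (i < nr && lab[q + 1L] > 0L) nb <- c(nb, lab[q + 1L])
      }
    }
    if (!length(nb)) {
      nlab <- nlab + 1L
      parent[nlab] <- nlab
      lab[p] <- nlab
    } else {
      roots <- unique(vapply(nb, find, 0L))
      m <- min(roots)
      lab[p] <- m
      for (r in roots[roots != m]) parent[r] <- m
    }
  }
  roots <- vapply(seq_len(nlab), find, 0L)
  lab[idx] <- roots[lab[idx]]
  ids <- unique(lab[idx])
  lab[idx] <- match(lab[idx], ids)
  lab
}

#' NA-aware bilinear sampling of a gridded image
#'
#' Samples `values` (with `occupied` validity mask) at arbitrary points.
#' Weights of invalid neighbors are dropped and the rest renormalized; a
#' sample is NA when less than `min_weight` of the bilinear mass is valid.
#'
#' @param values numeric matrix (rows = x, cols = y).
#' @param occupied logical matrix, same dim.
#' @param xc,yc bin-center coordinate vectors (uniform spacing).
#' @param xs,ys sample coordinates (equal-length vectors).
#' @param min_weight minimum valid bilinear mass (default 0.5).
#' @return numeric vector of sampled values (NA where undefined).
#' @keywords internal
bilinear_sample <- function(values, occupied, xc, yc, xs, ys, min_weight = 0.5) {
  nr <- length(xc); nc <- length(yc)
  sx <- if (nr > 1) xc[2] - xc[1] else 1
  sy <- if (nc > 1) yc[2] - yc[1] else 1
  fx <- (xs - xc[1]) / sx; fy <- (ys - yc[1]) / sy
  i0 <- floor(fx); j0 <- floor(fy)
  rx <- fx - i0; ry <- fy - j0
  acc_v <- numeric(length(xs)); acc_w <- numeric(length(xs))
  for (di in 0:1) for (dj in 0:1) {
    ii <- i0 + di + 1; jj <- j0 + dj + 1
    w <- (if (di == 0) 1 - rx else rx) * (if (dj == 0) 1 - ry else ry)
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc & w > 0
    idx <- (jj[ok] - 1L) * nr + ii[ok]
    occ <- occupied[idx] & !is.na(values[idx])
    ok[ok] <- occ
    idx <- idx[occ]
    acc_v[ok] <- acc_v[ok] + w[ok] * values[idx]
    acc_w[ok] <- acc_w[ok] + w[ok]
  }
  out <- ifelse(acc_w >= min_weight, acc_v / pmax(acc_w, .Machine$double.eps), NA_real_)
  out
}

# Masked cross-correlation sums via FFT. Returns, for every integer bin
# displacement d = (dx, dy), the sums over co-defined bins needed for a
# Pearson correlation between A[i, j] and B[i + dx, j + dy].
masked_xcorr_sums <- function(A, B) {
  MA <- !is.na(A); MB <- !is.na(B)
  A0 <- A; A0[!MA] <- 0
  B0 <- B; B0[!MB] <- 0
  nrA <- nrow(A); ncA <- ncol(A); nrB <- nrow(B); ncB <- ncol(B)
  P <- nrA + nrB - 1L; Q <- ncA + ncB - 1L
  pad <- function(m) { out <- matrix(0, P, Q); out[seq_len(nrow(m)), seq_len(ncol(m))] <- m; out }
  fa <- lapply(list(M = MA * 1, X = A0, X2 = A0^2), function(m) stats::fft(pad(m)))
  fb <- lapply(list(M = MB * 1, X = B0, X2 = B0^2), function(m) stats::fft(pad(m)))
  xc <- function(F, G) Re(stats::fft(Conj(F) * G, inverse = TRUE)) / (P * Q)
  dxs <- -(nrA - 1L):(nrB - 1L)
  dys <- -(ncA - 1L):(ncB - 1L)
  ix <- (dxs %% P) + 1L; iy <- (dys %% Q) + 1L
  grab <- function(m) m[ix, iy, drop = FALSE]
  list(
    dx = dxs, dy = dys,
    n   = round(grab(xc(fa$M, fb$M))),
    sa  = grab(xc(fa$X, fb$M)),
    sb  = grab(xc(fa$M, fb$X)),
    sab = grab(xc(fa$X, fb$X)),
    saa = grab(xc(fa$X2, fb$M)),
    sbb = grab(xc(fa$M, fb$X2))
  )
}
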