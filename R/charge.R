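# Charge-cloud geometry: apportioning a uniform-density spherical cloud of
# radius r0 over square pixel columns.

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch Jacobi matrix
.gl_cache <- new.env(parent = emptyenv())
.gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  out <- list(nodes = rev(e$values), weights = rev(2 * e$vectors[1, ]^2))
  assign(key, out, envir = .gl_cache)
  out
}

# fraction of a uniform ball of radius R beyond the plane at signed
# distance t from its center (spherical cap volume fraction)
.cap_fraction <- function(t, R) {
  f <- (R - t)^2 * (2 * R + t) / (4 * R^3)
  ifelse(t <= -R, 1, ifelse(t >= R, 0, f))
}

# fraction of a uniform ball of radius R with X > a and Y > b; vectorized
# over (a, b). 1D quadrature of circular-segment areas over x.
.quadrant_fraction <- function(a, b, R, nodes = 64L) {
  if (R <= 0) stop("R must be > 0")
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  lo <- pmax(a, -R)
  out <- numeric(n)
  live <- lo < R
  if (!any(live)) return(out)
  gl <- .gauss_legendre(nodes)
  half <- (R - lo[live]) / 2
  mid <- (R + lo[live]) / 2
  x <- outer(half, gl$nodes) + mid          # n_live x nodes
  r2 <- pmax(R^2 - x^2, 0)
  r <- sqrt(r2)
  bb <- b[live]
  ratio <- pmin(pmax(bb / pmax(r, 1e-300), -1), 1)
  seg <- r2 * acos(ratio) - bb * sqrt(pmax(r2 - bb^2, 0))
  out[live] <- (seg %*% gl$weights) * half / (4 / 3 * pi * R^3)
  pmin(pmax(out, 0), 1)
}

#' Charge fraction collected by a pixel
#'
#' Fraction of a uniform-density spherical charge cloud of radius `r0`
#' centered at `center` (coordinates in the frame of the central pixel,
#' which spans `[-pitch/2, pitch/2)` in x and y) that falls within the
#' pixel column at integer offset `(di, dj)`. Charge collection is
#' depth-independent: the cloud is apportioned by volume over the square
#' pixel columns.
#'
#' @param center numeric length-2 `(x, y)` in micrometers, or an n x 2
#'   matrix of centers.
#' @param r0 cloud radius in micrometers (>= 0).
#' @param offset integer length-2 `(di, dj)` pixel offset, or an n x 2
#'   matrix.
#' @param pitch pixel pitch in micrometers.
#' @return fraction(s) in `[0, 1]`.
#' @export
charge_fraction <- function(center, r0, offset, pitch = 55) {
  center <- matrix(as.numeric(center), ncol = 2)
  offset <- matrix(as.numeric(offset), ncol = 2)
  n <- max(nrow(center), nrow(offset))
  cx <- rep_len(center[, 1], n); cy <- rep_len(center[, 2], n)
  ox <- rep_len(offset[, 1], n); oy <- rep_len(offset[, 2], n)
  x1 <- ox * pitch - pitch / 2; x2 <- x1 + pitch
  y1 <- oy * pitch - pitch / 2; y2 <- y1 + pitch
  if (r0 == 0) {
    return(as.numeric(cx >= x1 & cx < x2 & cy >= y1 & cy < y2))
  }
  q <- function(a, b) .quadrant_fraction(a, b, r0)
  f <- q(x1 - cx, y1 - cy) - q(x2 - cx, y1 - cy) -
       q(x1 - cx, y2 - cy) + q(x2 - cx, y2 - cy)
  pmin(pmax(f, 0), 1)
}

# Fast path used by both engines: a cloud with r0 < pitch/2 overlaps at
# most a 2x2 pixel block. Returns, per cloud center, the pixel (u, v)
# containing the center, the signed directions (sx, sy) of the nearest
# vertical/horizontal pixel edges, and the volume fractions assigned to
# the center pixel, the x-neighbor (u + sx, v), the y-neighbor
# (u, v + sy), and the diagonal neighbor (u + sx, v + sy).
.cloud_block_fractions <- function(cx, cy, r0, pitch) {
  if (r0 >= pitch / 2)
    stop("charge-cloud radius must be smaller than half the pixel pitch")
  u <- round(cx / pitch); v <- round(cy / pitch)
  lx <- cx - u * pitch; ly <- cy - v * pitch
  sx <- ifelse(lx >= 0, 1, -1); sy <- ifelse(ly >= 0, 1, -1)
  tx <- pitch / 2 - abs(lx); ty <- pitch / 2 - abs(ly)
  if (r0 == 0) {
    z <- numeric(length(cx))
    return(list(u = u, v = v, sx = sx, sy = sy,
                f_c = z + 1, f_x = z, f_y = z, f_xy = z))
  }
  capx <- .cap_fraction(tx, r0)
  capy <- .cap_fraction(ty, r0)
  Q <- numeric(length(cx))
  need <- tx * tx + ty * ty < r0 * r0
  if (any(need)) Q[need] <- .quadrant_fraction(tx[need], ty[need], r0)
  list(u = u, v = v, sx = sx, sy = sy,
       f_c = 1 - capx - capy + Q, f_x = capx - Q, f_y = capy - Q, f_xy = Q)
}

# charge split table on an n x n lattice of in-pixel positions: for a cloud
# centered at lattice midpoint p of a pixel, fractions collected by the
# 3x3 block of pixels centered on that pixel (columns in .offsets3 order).
.split_table <- function(n, r0, pitch) {
  step <- pitch / n
  pos <- (seq_len(n) - 0.5) * step - pitch / 2
  g <- expand.grid(x = pos, y = pos)  # position index p = ix + n*(iy-1)
  bl <- .cloud_block_fractions(g$x, g$y, r0, pitch)
  S <- matrix(0, nrow = n * n, ncol = 9)
  idx9 <- function(di, dj) (dj + 1) * 3 + (di + 1) + 1
  rows <- seq_len(n * n)
  S[cbind(rows, idx9(0, 0))] <- bl$f_c
  S[cbind(rows, idx9(bl$sx, 0))] <- S[cbind(rows, idx9(bl$sx, 0))] + bl$f_x
  S[cbind(rows, idx9(0, bl$sy))] <- S[cbind(rows, idx9(0, bl$sy))] + bl$f_y
  S[cbind(rows, idx9(bl$sx, bl$sy))] <- S[cbind(rows, idx9(bl$sx, bl$sy))] + bl$f_xy
  S
}
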