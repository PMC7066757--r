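# Interpolation engines.
#
# All samplers take continuous 0-based voxel indices (n x 3) and return one
# value per point; anything outside [0, dim-1] on any axis gets `fill`.

interp_at <- function(arr, idx, method = c("linear", "nearest",
                                           "cubic_bspline"),
                      fill = 0, coefs = NULL) {
  method <- match.arg(method)
  switch(method,
         nearest = interp_nearest(arr, idx, fill),
         linear = interp_linear(arr, idx, fill)$value,
         cubic_bspline = interp_cubic(arr, idx, fill, coefs))
}

interp_nearest <- function(arr, idx, fill = 0) {
  d <- dim(arr)
  i <- round(idx[, 1]); j <- round(idx[, 2]); k <- round(idx[, 3])
  ok <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 &
    k >= 0 & k <= d[3] - 1
  out <- rep(fill, nrow(idx))
  if (any(ok))
    out[ok] <- arr[1L + i[ok] + d[1] * (j[ok] + d[2] * k[ok])]
  out
}

# Trilinear interpolation; also returns the spatial derivative (per unit
# voxel index) so metric gradients can reuse the same eight corner fetches.
interp_linear <- function(arr, idx, fill = 0, want_grad = FALSE) {
  d <- dim(arr)
  n <- nrow(idx)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  ok <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    z >= 0 & z <= d[3] - 1
  value <- rep(fill, n)
  grad <- if (want_grad) matrix(0, n, 3) else NULL
  if (any(ok)) {
    x <- x[ok]; y <- y[ok]; z <- z[ok]
    i0 <- pmin(floor(x), d[1] - 2); i0 <- pmax(i0, 0)
    j0 <- pmin(floor(y), d[2] - 2); j0 <- pmax(j0, 0)
    k0 <- pmin(floor(z), d[3] - 2); k0 <- pmax(k0, 0)
    tx <- x - i0; ty <- y - j0; tz <- z - k0
    base <- 1L + i0 + d[1] * (j0 + d[2] * k0)
    o1 <- 1L; o2 <- d[1]; o3 <- d[1] * d[2]
    c000 <- arr[base];            c100 <- arr[base + o1]
    c010 <- arr[base + o2];       c110 <- arr[base + o1 + o2]
    c001 <- arr[base + o3];       c101 <- arr[base + o1 + o3]
    c011 <- arr[base + o2 + o3];  c111 <- arr[base + o1 + o2 + o3]
    c00 <- c000 + tx * (c100 - c000)
    c10 <- c010 + tx * (c110 - c010)
    c01 <- c001 + tx * (c101 - c001)
    c11 <- c011 + tx * (c111 - c011)
    c0 <- c00 + ty * (c10 - c00)
    c1 <- c01 + ty * (c11 - c01)
    value[ok] <- c0 + tz * (c1 - c0)
    if (want_grad) {
      # d/dx at fixed ty, tz
      gx00 <- c100 - c000; gx10 <- c110 - c010
      gx01 <- c101 - c001; gx11 <- c111 - c011
      gx0 <- gx00 + ty * (gx10 - gx00)
      gx1 <- gx01 + ty * (gx11 - gx01)
      g1 <- gx0 + tz * (gx1 - gx0)
      g2 <- (c10 - c00) + tz * ((c11 - c01) - (c10 - c00))
      g3 <- c1 - c0
      grad[ok, ] <- cbind(g1, g2, g3)
    }
  }
  list(value = value, inside = ok, grad = grad)
}

# --- cubic B-spline interpolation with recursive prefiltering -------------

# Direct B-spline transform (Unser): turns samples into B-spline
# coefficients so that the cubic spline interpolates the data exactly.
bspline_prefilter <- function(arr) {
  z <- sqrt(3) - 2
  d <- dim(arr)
  filt <- function(M) {
    # filter along rows of an n x m matrix, all columns at once
    n <- nrow(M)
    if (n == 1L) return(M)
    lambda <- (1 - z) * (1 - 1 / z)
    M <- M * lambda
    K <- min(n, ceiling(log(1e-12) / log(abs(z))))
    zk <- z^(seq_len(K) - 1)
    C <- M
    C[1, ] <- as.numeric(zk %*% M[seq_len(K), , drop = FALSE])
    for (i in 2:n) C[i, ] <- M[i, ] + z * C[i - 1, ]
    C[n, ] <- (z / (z * z - 1)) * (C[n, ] + z * C[n - 1, ])
    for (i in (n - 1):1) C[i, ] <- z * (C[i + 1, ] - C[i, ])
    C
  }
  a <- arr
  a <- array(filt(matrix(a, d[1], d[2] * d[3])), d)
  a <- aperm(a, c(2, 1, 3))
  a <- array(filt(matrix(a, d[2], d[1] * d[3])), d[c(2, 1, 3)])
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 1, 2))
  a <- array(filt(matrix(a, d[3], d[1] * d[2])), d[c(3, 1, 2)])
  aperm(a, c(2, 3, 1))
}

# cubic B-spline basis values for fractional offsets t in [0, 1); returns
# the four weights for knots at offsets -1, 0, 1, 2
cubic_bspline_weights <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  cbind((1 - t)^3 / 6,
        (3 * t3 - 6 * t2 + 4) / 6,
        (-3 * t3 + 3 * t2 + 3 * t + 1) / 6,
        t3 / 6)
}

# derivative of the four cubic basis functions w.r.t. t
cubic_bspline_dweights <- function(t) {
  t2 <- t * t
  cbind(-(1 - t)^2 / 2,
        (3 * t2 - 4 * t) / 2,
        (-3 * t2 + 2 * t + 1) / 2,
        t2 / 2)
}

interp_cubic <- function(arr, idx, fill = 0, coefs = NULL) {
  if (is.null(coefs)) coefs <- bspline_prefilter(arr)
  d <- dim(arr)
  n <- nrow(idx)
  out <- rep(fill, n)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  ok <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    z >= 0 & z <= d[3] - 1
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  i0 <- floor(x); j0 <- floor(y); k0 <- floor(z)
  wx <- cubic_bspline_weights(x - i0)
  wy <- cubic_bspline_weights(y - j0)
  wz <- cubic_bspline_weights(z - k0)
  acc <- numeric(length(x))
  for (a in 0:3) {
    # mirror out-of-range support indices back into the grid
    ia <- reflect_index(i0 + a - 1, d[1])
    for (b in 0:3) {
      jb <- reflect_index(j0 + b - 1, d[2])
      wab <- wx[, a + 1] * wy[, b + 1]
      for (cc in 0:3) {
        kc <- reflect_index(k0 + cc - 1, d[3])
        acc <- acc + wab * wz[, cc + 1] *
          coefs[1L + ia + d[1] * (jb + d[2] * kc)]
      }
    }
  }
  out[ok] <- acc
  out
}

# mirror boundary (whole-sample symmetry), consistent with the prefilter
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  p <- 2L * (n - 1L)
  i <- ((i %% p) + p) %% p
  ifelse(i >= n, p - i, i)
}
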