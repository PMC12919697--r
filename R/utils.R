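# Small numeric helpers shared across modules. All grids are uniform.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Linear interpolation on a uniform grid y[k] at x0 + (k-1)*dx.
# Outside the grid the value is `outside` (default 0).
lin_lookup <- function(x0, dx, y, xout, outside = 0) {
  n <- length(y)
  t <- (xout - x0) / dx
  k <- floor(t)
  f <- t - k
  ok <- k >= 0 & k <= n - 1
  k1 <- clamp(k + 1L, 1L, n)
  k2 <- clamp(k + 2L, 1L, n)
  v <- (1 - f) * y[k1] + f * y[k2]
  v[!ok] <- outside
  v
}

# Bilinear interpolation of matrix M (rows = u axis, cols = v axis) with
# uniform axes u0 + (i-1)*du, v0 + (j-1)*dv, at query points (uq, vq).
# Points outside the grid evaluate to `outside`.
bilinear_lookup <- function(M, u0, du, v0, dv, uq, vq, outside = 0) {
  nu <- nrow(M); nv <- ncol(M)
  ti <- (uq - u0) / du
  tj <- (vq - v0) / dv
  i <- floor(ti); j <- floor(tj)
  fi <- ti - i; fj <- tj - j
  ok <- i >= 0 & i <= nu - 1 & j >= 0 & j <= nv - 1
  i1 <- clamp(i + 1L, 1L, nu); i2 <- clamp(i + 2L, 1L, nu)
  j1 <- clamp(j + 1L, 1L, nv); j2 <- clamp(j + 2L, 1L, nv)
  v <- (1 - fi) * (1 - fj) * M[cbind(i1, j1)] +
    fi * (1 - fj) * M[cbind(i2, j1)] +
    (1 - fi) * fj * M[cbind(i1, j2)] +
    fi * fj * M[cbind(i2, j2)]
  v[!ok] <- outside
  v
}

# Discrete Gaussian kernel sampled at pixel centers, normalized to sum 1.
gauss_kernel <- function(sigma_px, halfwidth_factor = 4) {
  if (sigma_px <= 0) return(1)
  h <- max(1L, ceiling(halfwidth_factor * sigma_px))
  x <- (-h):h
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Separable Gaussian convolution of matrix M (zero padding outside),
# same-size output. sigma in pixel units per axis.
conv_gauss_same <- function(M, sigma_u_px, sigma_v_px = sigma_u_px) {
  if (sigma_u_px <= 0 && sigma_v_px <= 0) return(M)
  conv1 <- function(A, k) {
    # convolve along rows (first dim) of A with kernel k, same size
    if (length(k) == 1) return(A)
    n <- nrow(A)
    h <- (length(k) - 1L) / 2L
    K <- matrix(0, n, n)
    for (o in -h:h) {
      idx <- seq_len(n)
      src <- idx + o
      keep <- src >= 1 & src <= n
      K[cbind(idx[keep], src[keep])] <- k[o + h + 1L]
    }
    K %*% A
  }
  M1 <- conv1(M, gauss_kernel(sigma_u_px))
  t(conv1(t(M1), gauss_kernel(sigma_v_px)))
}

# Separable Gaussian convolution with "full" output: the output grid
# extends the input grid by the kernel half-width on each side of both
# axes. Returns list(M, pad_u, pad_v) with pads in pixels.
conv_gauss_full <- function(M, sigma_px) {
  if (sigma_px <= 0) return(list(M = M, pad = 0L))
  k <- gauss_kernel(sigma_px)
  h <- (length(k) - 1L) / 2L
  bandmat <- function(n_in) {
    n_out <- n_in + 2L * h
    K <- matrix(0, n_out, n_in)
    for (o in seq_along(k)) {
      i_out <- seq_len(n_in) + (o - 1L)
      K[cbind(i_out, seq_len(n_in))] <- k[length(k) - o + 1L]
    }
    K
  }
  Ku <- bandmat(nrow(M))
  Kv <- bandmat(ncol(M))
  list(M = Ku %*% M %*% t(Kv), pad = h)
}

# FNV-1a style hash of a serialized R object, for run provenance.
config_hash <- function(x) {
  b <- as.integer(serialize(x, NULL))
  h <- 2166136261
  for (i in seq_along(b)) {
    h <- bitwXor(as.integer(h %% 2^31), b[i])
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
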