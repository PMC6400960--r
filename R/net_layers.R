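# Layer primitives for the direct reconstruction network.
#
# Activations are matrices of shape channels x (npix * batch), columns
# ordered pixel-fastest then sample. In this layout a convolution kernel tap
# is a constant column offset, so convolutions reduce to contiguous
# column-block shifts plus one small dgemm per tap, and per-channel
# operations (bias, batch norm) are first-dimension vector recycling. All
# plain double-precision BLAS, so gradients can be finite-difference checked.

# tap geometry for a same-padded ksize x ksize convolution on a side x side
# grid: each tap k has a column offset `delta` and the set of output columns
# `bad` whose source pixel falls outside the frame.
conv_geom <- function(side, ksize, B) {
  if (ksize %% 2 != 1) stop("kernel size must be odd")
  npix <- side * side
  r <- (ksize - 1L) %/% 2L
  p <- seq_len(npix)
  i <- ((p - 1L) %% side) + 1L
  j <- ((p - 1L) %/% side) + 1L
  offs <- expand.grid(di = -r:r, dj = -r:r)
  K <- nrow(offs)
  boff <- rep((seq_len(B) - 1L) * npix, each = npix)
  taps <- vector("list", K)
  for (k in seq_len(K)) {
    ip <- i + offs$di[k]; jp <- j + offs$dj[k]
    delta <- offs$di[k] + offs$dj[k] * side
    out_of_frame <- ip < 1L | ip > side | jp < 1L | jp > side
    bad1 <- p[out_of_frame]
    bad <- if (length(bad1)) rep(bad1, B) + boff[rep(out_of_frame, B)]
           else integer(0)
    badm <- bad + delta            # masked columns as seen by the -delta-shifted
    badm <- badm[badm >= 1L & badm <= npix * B]   # upstream gradient
    taps[[k]] <- list(delta = as.integer(delta), bad = bad, badm = badm)
  }
  list(taps = taps, K = K, npixB = npix * B, side = side, B = B,
       ksize = ksize)
}

# Z[, c] = A[, c + delta] (zero outside), then Z[, bad] = 0.
shift_cols <- function(A, delta, bad = integer(0)) {
  n <- ncol(A)
  if (delta == 0L) {
    Z <- A
  } else {
    Z <- matrix(0, nrow(A), n)
    if (delta > 0L) {
      if (delta < n) Z[, seq_len(n - delta)] <- A[, (1L + delta):n, drop = FALSE]
    } else {
      d <- -delta
      if (d < n) Z[, (1L + d):n] <- A[, seq_len(n - d), drop = FALSE]
    }
  }
  if (length(bad)) Z[, bad] <- 0
  Z
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

conv2d_init <- function(cin, cout, ksize) {
  list(W = he_init(ksize * ksize * cin, cout, ksize * ksize * cin),
       b = numeric(cout), ksize = ksize, cin = cin, cout = cout)
}

conv2d_fwd <- function(M, par, geom) {
  if (par$ksize == 1L)
    return(list(out = crossprod(par$W, M) + par$b, cache = M))
  cin <- par$cin
  Y <- NULL
  for (k in seq_len(geom$K)) {
    tap <- geom$taps[[k]]
    Wk <- par$W[((k - 1L) * cin + 1L):(k * cin), , drop = FALSE]
    Tk <- crossprod(Wk, shift_cols(M, tap$delta, tap$bad))
    Y <- if (is.null(Y)) Tk else Y + Tk
  }
  list(out = Y + par$b, cache = M)
}

conv2d_bwd <- function(dY, cache, par, geom) {
  M <- cache
  db <- rowSums(dY)
  if (par$ksize == 1L)
    return(list(dM = par$W %*% dY, dW = tcrossprod(M, dY), db = db))
  cin <- par$cin
  dW <- matrix(0, geom$K * cin, par$cout)
  dM <- matrix(0, cin, geom$npixB)
  for (k in seq_len(geom$K)) {
    tap <- geom$taps[[k]]
    rows <- ((k - 1L) * cin + 1L):(k * cin)
    Wk <- par$W[rows, , drop = FALSE]
    # one shift per tap: column shifts commute with left-multiplication, so
    # both the weight and input gradients read off the shifted masked dY
    S <- shift_cols(dY, -tap$delta, tap$badm)
    dW[rows, ] <- tcrossprod(M, S)
    dM <- dM + Wk %*% S
  }
  list(dM = dM, dW = dW, db = db)
}

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

bn_fwd <- function(M, par, training, eps = 1e-5, momentum = 0.9) {
  if (training) {
    mu <- rowMeans(M)
    v <- rowMeans(M * M) - mu^2
    v[v < 0] <- 0
    new_run <- list(run_mean = momentum * par$run_mean + (1 - momentum) * mu,
                    run_var = momentum * par$run_var + (1 - momentum) * v)
  } else {
    mu <- par$run_mean; v <- par$run_var
    new_run <- NULL
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (M - mu) * invstd
  out <- xhat * par$gamma + par$beta
  list(out = out, cache = list(xhat = xhat, invstd = invstd, gamma = par$gamma),
       new_run = new_run)
}

bn_bwd <- function(dY, cache) {
  xhat <- cache$xhat
  dgamma <- rowSums(dY * xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * cache$gamma
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dM <- (dxhat - m1 - xhat * m2) * cache$invstd
  list(dM = dM, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(M) list(out = pmax(M, 0), cache = M > 0)
relu_bwd <- function(dY, cache) dY * cache

# Gate-shared fully connected measurement -> pixel mapping, with the
# transpose that brings pixel maps in front of the gate dimension.
# The effective weight is `scale * W`: `scale` is a fixed constant chosen at
# initialization so the trainable tensor W is O(1). Adaptive optimizers take
# roughly lr-sized absolute steps per parameter, and the physically
# meaningful mapping (a pseudo-inverse with entries ~ 1/n_meas) would
# otherwise be wiped out within one epoch.
fc_init <- function(n_meas, npix) {
  scale <- sqrt(2 / n_meas)
  list(W = matrix(stats::rnorm(n_meas * npix), n_meas, npix),
       b = numeric(npix), scale = scale)
}

fc_fwd <- function(X, par) {
  # X: array (B, G, n_meas) -> out: G x (npix * B)
  B <- dim(X)[1]; G <- dim(X)[2]; n_meas <- dim(X)[3]
  Min <- matrix(aperm(X, c(3, 2, 1)), n_meas, G * B)
  Y <- par$scale * crossprod(par$W, Min) + par$b   # npix x (G * B)
  npix <- nrow(Y)
  out <- matrix(aperm(array(Y, c(npix, G, B)), c(2, 1, 3)), G, npix * B)
  list(out = out, cache = list(Min = Min, G = G, B = B, npix = npix,
                               scale = par$scale))
}

fc_bwd <- function(dOut, cache) {
  G <- cache$G; B <- cache$B; npix <- cache$npix
  dY <- matrix(aperm(array(dOut, c(G, npix, B)), c(2, 1, 3)), npix, G * B)
  list(dW = cache$scale * tcrossprod(cache$Min, dY), db = rowSums(dY))
}

# 1D convolution along the gate-channel axis, per pixel
conv1d_init <- function(G, kernel, stride, filters) {
  L <- (G - kernel) %/% stride + 1L
  if (L < 1) stop("conv1d kernel longer than the gate axis")
  list(W = he_init(kernel, filters, kernel), b = numeric(filters),
       kernel = kernel, stride = stride, filters = filters, L = L, G = G)
}

conv1d_fwd <- function(M, par) {
  L <- par$L; F_ <- par$filters
  Y <- matrix(0, L * F_, ncol(M))
  for (j in seq_len(L)) {
    rows <- (par$stride * (j - 1L) + 1L):(par$stride * (j - 1L) + par$kernel)
    Y[((j - 1L) * F_ + 1L):(j * F_), ] <-
      crossprod(par$W, M[rows, , drop = FALSE]) + par$b
  }
  list(out = Y, cache = M)
}

conv1d_bwd <- function(dY, cache, par) {
  M <- cache
  L <- par$L; F_ <- par$filters
  dW <- matrix(0, par$kernel, F_); db <- numeric(F_)
  dM <- matrix(0, nrow(M), ncol(M))
  for (j in seq_len(L)) {
    rows <- (par$stride * (j - 1L) + 1L):(par$stride * (j - 1L) + par$kernel)
    dYj <- dY[((j - 1L) * F_ + 1L):(j * F_), , drop = FALSE]
    dW <- dW + tcrossprod(M[rows, , drop = FALSE], dYj)
    db <- db + rowSums(dYj)
    dM[rows, ] <- dM[rows, , drop = FALSE] + par$W %*% dYj
  }
  list(dM = dM, dW = dW, db = db)
}
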