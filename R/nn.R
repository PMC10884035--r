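# Minimal CNN primitives for the segmentation network. Feature maps are
# numeric arrays (H, W, C); convolution runs through the compiled
# im2col+BLAS kernels; every primitive has a hand-derived backward pass
# (checked against finite differences in the test suite).

as_cube <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

nn_conv_fwd <- function(x, W, b, stride = 1L, pad = 1L) {
  k <- dim(W)[1]
  cpp_conv2d_fwd(as_cube(x), matrix(W, k * k * dim(W)[3], dim(W)[4]),
                 b, k, stride, pad)
}

nn_conv_bwd <- function(x, W, dy, stride = 1L, pad = 1L) {
  k <- dim(W)[1]
  r <- cpp_conv2d_bwd(as_cube(x), matrix(W, k * k * dim(W)[3], dim(W)[4]),
                      as_cube(dy), k, stride, pad)
  list(dx = r$dx, dW = array(r$dw, dim(W)), db = as.numeric(r$db))
}

# Largest group count <= requested that divides the channel count.
gn_ngroups <- function(C, groups) {
  g <- min(groups, C)
  while (C %% g != 0L) g <- g - 1L
  g
}

gn_fwd <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]
  g <- gn_ngroups(C, groups)
  n <- HW * (C / g)
  xm <- matrix(x, n, g)
  mu <- colMeans(xm)
  va <- colMeans(xm * xm) - mu^2
  sdv <- sqrt(va + eps)
  xhat <- (xm - rep(mu, each = n)) / rep(sdv, each = n)
  y <- array(xhat, d) * rep(gamma, each = HW) + rep(beta, each = HW)
  list(y = y, xhat = xhat, sdv = sdv, g = g, dims = d)
}

gn_bwd <- function(dy, gamma, cache) {
  d <- cache$dims; HW <- d[1] * d[2]; C <- d[3]; g <- cache$g
  n <- HW * (C / g)
  dyv <- as.numeric(dy)
  xhat_full <- as.numeric(cache$xhat)
  dgamma <- colSums(matrix(dyv * xhat_full, HW, C))
  dbeta <- colSums(matrix(dyv, HW, C))
  dxhat <- matrix(dyv * rep(gamma, each = HW), n, g)
  xh <- cache$xhat
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xh)
  dx <- (dxhat - rep(m1, each = n) - xh * rep(m2, each = n)) /
    rep(cache$sdv, each = n)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

# Bilinear interpolation matrix mapping n_in samples to n_out (pixel-centre
# convention); cached per size pair.
.bilin_cache <- new.env(parent = emptyenv())
bilin_mat <- function(n_in, n_out) {
  key <- paste0(n_in, "_", n_out)
  hit <- get0(key, envir = .bilin_cache)
  if (!is.null(hit)) return(hit)
  src <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  i0 <- floor(src)
  fr <- src - i0
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    A[i, i0[i] + 1] <- A[i, i0[i] + 1] + (1 - fr[i])
    A[i, min(i0[i] + 2, n_in)] <- A[i, min(i0[i] + 2, n_in)] + fr[i]
  }
  assign(key, A, envir = .bilin_cache)
  A
}

up2_fwd <- function(x) {
  d <- dim(x)
  A <- bilin_mat(d[1], 2L * d[1])
  B <- bilin_mat(d[2], 2L * d[2])
  out <- array(0, c(2L * d[1], 2L * d[2], d[3]))
  for (c in seq_len(d[3])) out[, , c] <- A %*% x[, , c] %*% t(B)
  out
}

up2_bwd <- function(dy, in_dims) {
  A <- bilin_mat(in_dims[1], 2L * in_dims[1])
  B <- bilin_mat(in_dims[2], 2L * in_dims[2])
  dx <- array(0, in_dims)
  for (c in seq_len(in_dims[3])) dx[, , c] <- t(A) %*% dy[, , c] %*% B
  dx
}

# Channel-wise (spatial) dropout; returns the scaled keep mask.
spatial_dropout_mask <- function(C, rate) {
  keep <- runif(C) >= rate
  keep / max(1e-12, 1 - rate)
}

sigmoid <- function(z) 1 / (1 + exp(-z))
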