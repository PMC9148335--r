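# Low-level differentiable layers. An activation tensor of N slices of size
# H x W with C channels is held as a (H*W*N) x C matrix (row index
# h + H*w + H*W*n), so batch norm is column arithmetic, channel
# concatenation is cbind, and 1x1 convolutions are plain matrix products.
# Convolution weights are (k*k*C_in, C_out) matrices.

conv_init <- function(k, cin, cout) {
  W <- matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
              k * k * cin, cout)
  attr(W, "k") <- as.integer(k)
  list(W = W, b = numeric(cout))
}

conv_fwd <- function(m, W, b, k, hw) {
  cols <- if (k == 1) m else im2col_cm(m, hw[1], hw[2], hw[3], k)
  y <- cols %*% W
  y <- y + rep(b, each = nrow(y))
  list(y = y, cols = cols)
}

conv_bwd <- function(dy, cols, W, k, cin, hw) {
  dW <- crossprod(cols, dy)
  db <- colSums(dy)
  dcols <- tcrossprod(dy, W)
  dx <- if (k == 1) dcols else col2im_cm(dcols, hw[1], hw[2], hw[3], k, cin)
  list(dx = dx, dW = dW, db = db)
}

bn_init <- function(c) list(gamma = rep(1, c), beta = numeric(c))

bn_fwd <- function(m, gamma, beta, state, training, momentum = 0.1,
                   eps = 1e-5) {
  n <- nrow(m)
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(m * m) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean; v <- state$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (m - rep(mu, each = n)) * rep(invstd, each = n)
  y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(y = y, cache = list(xhat = xhat, invstd = invstd,
                           training = training),
       state = state)
}

bn_bwd <- function(dy, gamma, cache) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  if (cache$training) {
    dxhat <- dy * rep(gamma, each = n)
    sx <- colSums(dxhat)
    sxx <- colSums(dxhat * cache$xhat)
    dx <- (dxhat - rep(sx / n, each = n) -
             cache$xhat * rep(sxx / n, each = n)) *
      rep(cache$invstd, each = n)
  } else {
    dx <- dy * rep(gamma * cache$invstd, each = n)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

prelu_fwd <- function(m, a) {
  pos <- (m > 0) + 0
  list(y = m * (pos + a * (1 - pos)), pos = pos, x = m)
}

prelu_bwd <- function(dy, a, cache) {
  negpart <- dy * (1 - cache$pos)
  list(dx = dy * cache$pos + a * negpart, da = sum(negpart * cache$x))
}

pool_fwd <- function(m, hw) {
  r <- maxpool2_cm(m, hw[1], hw[2], hw[3])
  list(y = r$y, idx = r$idx, nrow_in = nrow(m))
}

pool_bwd <- function(dy, idx, nrow_in, cin) {
  dx <- matrix(0, nrow_in, cin)
  dx[as.vector(idx)] <- as.vector(dy)   # indices are unique per pool window
  dx
}

unpool_fwd <- function(y, idx, nrow_out, cin) {
  x <- matrix(0, nrow_out, cin)
  x[as.vector(idx)] <- as.vector(y)
  x
}

unpool_bwd <- function(dx, idx) {
  dy <- dx[as.vector(idx)]
  dim(dy) <- dim(idx)
  dy
}

softmax_rows <- function(m) {
  mx <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, j])
  e <- exp(m - mx)
  e / rowSums(e)
}
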