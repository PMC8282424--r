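# A compact neural-network engine: 2-D convolutions (im2col), ReLU, 2x2
# max pooling, nearest-neighbour upsampling, channel concatenation, global
# average pooling, dense layers, a softmax cross-entropy head, and Adam.
# Everything is plain R linear algebra; images are arrays (height, width,
# channels) and gradients are exact (validated by finite differences in the
# test suite). Sized for desk-scale problems: small images, narrow widths.

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

new_conv_params <- function(k, in_c, out_c) {
  list(W = he_init(c(k, k, in_c, out_c), k * k * in_c),
       b = numeric(out_c))
}

new_dense_params <- function(n_in, n_out) {
  list(W = he_init(c(n_in, n_out), n_in), b = numeric(n_out))
}

# reshape conv weights to the im2col matrix layout (channel fastest, then
# row offset, then col offset)
conv_wmat <- function(W) {
  matrix(aperm(W, c(3, 1, 2, 4)), ncol = dim(W)[4])
}

im2col <- function(x, k) {
  h <- dim(x)[1]; w <- dim(x)[2]; cc <- dim(x)[3]
  if (k == 1L) return(matrix(x, h * w, cc))
  p <- (k - 1L) %/% 2L
  P <- array(0, c(h + 2 * p, w + 2 * p, cc))
  P[(p + 1):(p + h), (p + 1):(p + w), ] <- x
  cols <- matrix(0, h * w, k * k * cc)
  blk <- 0L
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      sub <- P[di:(di + h - 1), dj:(dj + w - 1), , drop = FALSE]
      cols[, (blk * cc + 1):(blk * cc + cc)] <- matrix(sub, h * w, cc)
      blk <- blk + 1L
    }
  }
  cols
}

col2im <- function(dcols, h, w, cc, k) {
  if (k == 1L) return(array(dcols, c(h, w, cc)))
  p <- (k - 1L) %/% 2L
  G <- array(0, c(h + 2 * p, w + 2 * p, cc))
  blk <- 0L
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      G[di:(di + h - 1), dj:(dj + w - 1), ] <-
        G[di:(di + h - 1), dj:(dj + w - 1), ] +
        array(dcols[, (blk * cc + 1):(blk * cc + cc)], c(h, w, cc))
      blk <- blk + 1L
    }
  }
  G[(p + 1):(p + h), (p + 1):(p + w), , drop = FALSE]
}

conv_fwd <- function(x, par) {
  k <- dim(par$W)[1]
  cols <- im2col(x, k)
  out_mat <- sweep(cols %*% conv_wmat(par$W), 2, par$b, "+")
  out <- array(out_mat, c(dim(x)[1], dim(x)[2], dim(par$W)[4]))
  list(out = out, cache = list(cols = cols, dims = dim(x), k = k))
}

conv_bwd <- function(dout, par, cache) {
  k <- cache$k
  out_c <- dim(par$W)[4]
  dmat <- matrix(dout, ncol = out_c)
  dW <- array(crossprod(cache$cols, dmat), dim(par$W)[c(3, 1, 2, 4)])
  dW <- aperm(dW, c(2, 3, 1, 4))   # back to (k, k, in_c, out_c)
  db <- colSums(dmat)
  dcols <- dmat %*% t(conv_wmat(par$W))
  dx <- col2im(dcols, cache$dims[1], cache$dims[2], cache$dims[3], k)
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}
relu_bwd <- function(dout, mask) dout * mask

maxpool_fwd <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]
  stopifnot(h %% 2 == 0, w %% 2 == 0)
  a11 <- x[seq(1, h, 2), seq(1, w, 2), , drop = FALSE]
  a21 <- x[seq(2, h, 2), seq(1, w, 2), , drop = FALSE]
  a12 <- x[seq(1, h, 2), seq(2, w, 2), , drop = FALSE]
  a22 <- x[seq(2, h, 2), seq(2, w, 2), , drop = FALSE]
  out <- pmax(a11, a21, a12, a22)
  m11 <- a11 == out
  m21 <- (a21 == out) & !m11
  m12 <- (a12 == out) & !(m11 | m21)
  m22 <- (a22 == out) & !(m11 | m21 | m12)
  list(out = out, cache = list(m = list(m11, m21, m12, m22), dims = dim(x)))
}

maxpool_bwd <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  m <- cache$m
  dx[seq(1, d[1], 2), seq(1, d[2], 2), ] <- dout * m[[1]]
  dx[seq(2, d[1], 2), seq(1, d[2], 2), ] <-
    dx[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] + dout * m[[2]]
  dx[seq(1, d[1], 2), seq(2, d[2], 2), ] <-
    dx[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] + dout * m[[3]]
  dx[seq(2, d[1], 2), seq(2, d[2], 2), ] <-
    dx[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE] + dout * m[[4]]
  dx
}

upsample_fwd <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]; cc <- dim(x)[3]
  out <- array(0, c(2 * h, 2 * w, cc))
  out[seq(1, 2 * h, 2), seq(1, 2 * w, 2), ] <- x
  out[seq(2, 2 * h, 2), seq(1, 2 * w, 2), ] <- x
  out[seq(1, 2 * h, 2), seq(2, 2 * w, 2), ] <- x
  out[seq(2, 2 * h, 2), seq(2, 2 * w, 2), ] <- x
  out
}

upsample_bwd <- function(dout) {
  h2 <- dim(dout)[1]; w2 <- dim(dout)[2]
  dout[seq(1, h2, 2), seq(1, w2, 2), , drop = FALSE] +
    dout[seq(2, h2, 2), seq(1, w2, 2), , drop = FALSE] +
    dout[seq(1, h2, 2), seq(2, w2, 2), , drop = FALSE] +
    dout[seq(2, h2, 2), seq(2, w2, 2), , drop = FALSE]
}

gap_fwd <- function(x) {
  list(out = apply(x, 3, mean), cache = dim(x))
}
gap_bwd <- function(dout, dims) {
  array(rep(dout, each = dims[1] * dims[2]) / (dims[1] * dims[2]), dims)
}

dense_fwd <- function(x, par) {
  list(out = as.vector(crossprod(par$W, x)) + par$b, cache = x)
}
dense_bwd <- function(dout, par, x) {
  list(dx = as.vector(par$W %*% dout), dW = outer(x, dout), db = dout)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# combined softmax + cross-entropy for a matrix of logits (rows = items);
# returns mean loss and the gradient wrt logits
softmax_ce <- function(logits, onehot) {
  q <- softmax_rows(logits)
  n <- nrow(logits)
  loss <- -sum(onehot * log(pmax(q, 1e-12))) / n
  list(loss = loss, dlogits = (q - onehot) / n, probs = q)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  # zero state with exactly the shape/type of each parameter
  zeros <- function(p) {
    if (is.list(p)) lapply(p, zeros)
    else if (is.numeric(p)) p * 0
    else p          # non-parameter metadata carried alongside
  }
  list(m = zeros(params), v = zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      return(out)
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# elementwise addition of two nested parameter/gradient lists
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) return(mapply(grad_add, a, b, SIMPLIFY = FALSE))
  a + b
}

grad_scale <- function(a, s) {
  if (is.list(a)) return(lapply(a, grad_scale, s = s))
  a * s
}
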