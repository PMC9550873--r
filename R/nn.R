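# Minimal neural-network kernel used by the self-supervised pretrainer and
# the patch classifier. Weights live in nested named lists whose leaves are
# numeric arrays; batches are arrays dim c(N, H, W, C) in [0, 1].
#
# Everything here is plain matrix algebra (BLAS-backed) with hand-derived
# backward passes; no external autodiff. Gradients are validated against
# central finite differences in the test suite.

# ---- parameter-tree helpers -----------------------------------------------

# List-node attributes (e.g. the encoder class tag) ride along unchanged.
tree_map <- function(f, a) {
  if (is.list(a)) {
    r <- a
    for (i in seq_along(a)) r[[i]] <- tree_map(f, a[[i]])
    r
  } else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    if (!is.list(b) || length(a) != length(b))
      stop_invalid("parameter trees have different structure")
    r <- a
    for (i in seq_along(a)) r[[i]] <- tree_map2(f, a[[i]], b[[i]])
    r
  } else {
    if (length(a) != length(b))
      stop_invalid("parameter leaves have different shapes")
    f(a, b)
  }
}

tree_map3 <- function(f, a, b, c) {
  if (is.list(a)) {
    r <- a
    for (i in seq_along(a)) r[[i]] <- tree_map3(f, a[[i]], b[[i]], c[[i]])
    r
  } else f(a, b, c)
}

tree_zeros_like <- function(a) tree_map(function(x) { x[] <- 0; x }, a)
tree_add <- function(a, b) tree_map2(`+`, a, b)

# ---- layers ----------------------------------------------------------------

# 3x3 same-padding convolution, expressed as nine shifted matrix products so
# the inner loop is a BLAS call rather than per-pixel R code.
conv3_forward <- function(x, W, b) {
  d <- dim(x); N <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  Cout <- dim(W)[4]
  xpad <- array(0, c(N, H + 2L, Wd + 2L, Cin))
  xpad[, 2:(H + 1L), 2:(Wd + 1L), ] <- x
  out <- matrix(b, N * H * Wd, Cout, byrow = TRUE)
  for (di in 1:3) for (dj in 1:3) {
    xs <- xpad[, di:(di + H - 1L), dj:(dj + Wd - 1L), , drop = FALSE]
    out <- out + matrix(xs, ncol = Cin) %*% matrix(W[di, dj, , ], Cin, Cout)
  }
  list(out = array(out, c(N, H, Wd, Cout)), xpad = xpad)
}

conv3_backward <- function(dout, xpad, W, need_dx = TRUE) {
  d <- dim(dout); N <- d[1]; H <- d[2]; Wd <- d[3]; Cout <- d[4]
  Cin <- dim(W)[3]
  doutm <- matrix(dout, ncol = Cout)
  dW <- array(0, dim(W)); db <- colSums(doutm)
  dxpad <- if (need_dx) array(0, dim(xpad)) else NULL
  for (di in 1:3) for (dj in 1:3) {
    xs <- xpad[, di:(di + H - 1L), dj:(dj + Wd - 1L), , drop = FALSE]
    dW[di, dj, , ] <- crossprod(matrix(xs, ncol = Cin), doutm)
    if (need_dx) {
      dxs <- doutm %*% t(matrix(W[di, dj, , ], Cin, Cout))
      dxpad[, di:(di + H - 1L), dj:(dj + Wd - 1L), ] <-
        dxpad[, di:(di + H - 1L), dj:(dj + Wd - 1L), , drop = FALSE] +
        array(dxs, c(N, H, Wd, Cin))
    }
  }
  dx <- if (need_dx) dxpad[, 2:(H + 1L), 2:(Wd + 1L), , drop = FALSE] else NULL
  list(dW = dW, db = db, dx = dx)
}

# 2x2 max pooling (H and W must be even). The winner index is cached as an
# integer in 1..4 over the quarters so backward can route gradients.
maxpool2_forward <- function(x) {
  d <- dim(x); H <- d[2]; Wd <- d[3]
  o1 <- seq(1L, H, 2L); o2 <- seq(2L, H, 2L)
  p1 <- seq(1L, Wd, 2L); p2 <- seq(2L, Wd, 2L)
  q1 <- x[, o1, p1, , drop = FALSE]; q2 <- x[, o2, p1, , drop = FALSE]
  q3 <- x[, o1, p2, , drop = FALSE]; q4 <- x[, o2, p2, , drop = FALSE]
  out <- pmax(q1, q2, q3, q4)
  # first-winner tie break, fixed quarter order
  which4 <- 1L * (q1 == out) +
    2L * (q2 == out & q1 != out) +
    3L * (q3 == out & q1 != out & q2 != out) +
    4L * (q4 == out & q1 != out & q2 != out & q3 != out)
  list(out = out, which = which4)
}

maxpool2_backward <- function(dout, which4, in_dim) {
  H <- in_dim[2]; Wd <- in_dim[3]
  o1 <- seq(1L, H, 2L); o2 <- seq(2L, H, 2L)
  p1 <- seq(1L, Wd, 2L); p2 <- seq(2L, Wd, 2L)
  dx <- array(0, in_dim)
  dx[, o1, p1, ] <- dout * (which4 == 1L)
  dx[, o2, p1, ] <- dout * (which4 == 2L)
  dx[, o1, p2, ] <- dout * (which4 == 3L)
  dx[, o2, p2, ] <- dout * (which4 == 4L)
  dx
}

# Global average pooling (N,H,W,C) -> (N,C).
gap_forward <- function(x) {
  d <- dim(x)
  colSums(aperm(x, c(2, 3, 1, 4)), dims = 2) / (d[2] * d[3])
}

gap_backward <- function(dy, in_dim) {
  HW <- in_dim[2] * in_dim[3]
  a <- array(rep(as.vector(dy) / HW, each = HW),
             c(in_dim[2], in_dim[3], in_dim[1], in_dim[4]))
  aperm(a, c(3, 1, 2, 4))
}

# Batch normalization over rows of an (N, D) matrix; population variance.
bn_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- colMeans(x)
  v <- pmax(colMeans(x^2) - mu^2, 0)
  sd <- sqrt(v + eps)
  xhat <- sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xhat = xhat, sd = sd)
}

bn_backward <- function(dout, cache, gamma) {
  xhat <- cache$xhat; sd <- cache$sd
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(sweep(dxhat, 2, m1, "-") - sweep(xhat, 2, m2, "*"), 2, sd, "/")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- encoder: 4 conv blocks (conv3 -> ReLU -> maxpool2) + GAP -------------

#' Initialize the small convolutional patch encoder
#'
#' A four-block convolutional network (3x3 convolution, ReLU, 2x2 max
#' pooling per block) followed by global average pooling. The encoder maps a
#' patch of any spatial size divisible by `2^length(channels)` to a
#' representation vector of length `channels[length(channels)]`. The encoder
#' contract is pluggable: anything with the same `encoder_forward()` /
#' `encoder_backward()` surface can stand in for it.
#'
#' @param in_channels number of input channels (3 for RGB patches).
#' @param channels integer vector of output channels per block.
#' @return An encoder parameter tree (class `"sslheat_encoder"`). Weights are
#'   drawn from the current RNG stream (He-scaled normal); seed the stream
#'   with [with_seed()] or `set.seed()` for reproducibility.
#' @export
encoder_init <- function(in_channels = 3L, channels = c(8L, 16L, 32L, 64L)) {
  blocks <- vector("list", length(channels))
  cin <- in_channels
  for (i in seq_along(channels)) {
    cout <- channels[i]
    blocks[[i]] <- list(
      W = array(stats::rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
                c(3L, 3L, cin, cout)),
      b = numeric(cout))
    cin <- cout
  }
  structure(list(blocks = blocks), class = "sslheat_encoder",
            channels = channels, in_channels = in_channels)
}

encoder_out_dim <- function(enc) {
  dim(enc$blocks[[length(enc$blocks)]]$W)[4]
}

#' @rdname encoder_init
#' @param enc encoder parameter tree.
#' @param x batch array `c(N, H, W, C)`.
#' @param keep_cache keep intermediate activations for a backward pass.
#' @return `encoder_forward()`: list with `y`, the `(N, D)` representation
#'   matrix, and (if requested) `cache`.
#' @export
encoder_forward <- function(enc, x, keep_cache = FALSE) {
  nb <- length(enc$blocks)
  caches <- if (keep_cache) vector("list", nb) else NULL
  h <- x
  for (i in seq_len(nb)) {
    cv <- conv3_forward(h, enc$blocks[[i]]$W, enc$blocks[[i]]$b)
    mask <- cv$out > 0
    act <- cv$out * mask
    mp <- maxpool2_forward(act)
    if (keep_cache)
      caches[[i]] <- list(xpad = cv$xpad, mask = mask, act_dim = dim(act),
                          which = mp$which)
    h <- mp$out
  }
  y <- gap_forward(h)
  list(y = y, cache = if (keep_cache) list(blocks = caches, gap_dim = dim(h)))
}

#' @rdname encoder_init
#' @param cache cache from `encoder_forward(..., keep_cache = TRUE)`.
#' @param dy upstream gradient `(N, D)`.
#' @return `encoder_backward()`: gradient tree matching the encoder layout.
#' @export
encoder_backward <- function(enc, cache, dy) {
  nb <- length(enc$blocks)
  grads <- vector("list", nb)
  dh <- gap_backward(dy, cache$gap_dim)
  for (i in rev(seq_len(nb))) {
    bc <- cache$blocks[[i]]
    dact <- maxpool2_backward(dh, bc$which, bc$act_dim) * bc$mask
    cb <- conv3_backward(dact, bc$xpad, enc$blocks[[i]]$W, need_dx = i > 1L)
    grads[[i]] <- list(W = cb$dW, b = cb$db)
    dh <- cb$dx
  }
  list(blocks = grads)
}

# ---- 2-layer MLP with batch norm (projector / predictor) ------------------

mlp_init <- function(din, dhidden, dout) {
  list(W1 = matrix(stats::rnorm(din * dhidden, sd = sqrt(2 / din)), din, dhidden),
       b1 = numeric(dhidden),
       gamma = rep(1, dhidden), beta = numeric(dhidden),
       W2 = matrix(stats::rnorm(dhidden * dout, sd = sqrt(2 / dhidden)),
                   dhidden, dout),
       b2 = numeric(dout))
}

mlp_forward <- function(p, x, keep_cache = FALSE) {
  h <- sweep(x %*% p$W1, 2, p$b1, "+")
  bn <- bn_forward(h, p$gamma, p$beta)
  mask <- bn$out > 0
  a <- bn$out * mask
  out <- sweep(a %*% p$W2, 2, p$b2, "+")
  list(out = out,
       cache = if (keep_cache) list(x = x, bn = bn, mask = mask, a = a))
}

mlp_backward <- function(p, cache, dout) {
  dW2 <- crossprod(cache$a, dout)
  db2 <- colSums(dout)
  da <- dout %*% t(p$W2)
  dbn <- da * cache$mask
  bb <- bn_backward(dbn, cache$bn, p$gamma)
  dh <- bb$dx
  dW1 <- crossprod(cache$x, dh)
  db1 <- colSums(dh)
  dx <- dh %*% t(p$W1)
  list(grads = list(W1 = dW1, b1 = db1, gamma = bb$dgamma, beta = bb$dbeta,
                    W2 = dW2, b2 = db2),
       dx = dx)
}

# ---- linear head + softmax cross-entropy ----------------------------------

head_init <- function(din, nclass = 2L) {
  list(W = matrix(stats::rnorm(din * nclass, sd = 0.01), din, nclass),
       b = numeric(nclass))
}

head_forward <- function(p, y) sweep(y %*% p$W, 2, p$b, "+")

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# labels: integer class index (1-based). weights: per-class weights.
cross_entropy <- function(logits, labels, class_weights = NULL) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  w <- if (is.null(class_weights)) rep(1, n) else class_weights[labels]
  idx <- cbind(seq_len(n), labels)
  loss <- -sum(w * log(pmax(P[idx], 1e-12))) / sum(w)
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits * (w / sum(w))
  list(loss = loss, dlogits = dlogits, probs = P)
}

# ---- optimizers ------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  params <- tree_map3(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                      params, state$m, state$v)
  list(params = params, state = state)
}

sgd_init <- function(params) list(v = tree_zeros_like(params))

sgd_step <- function(params, grads, state, lr, momentum = 0.9) {
  state$v <- tree_map2(function(v, g) momentum * v + g, state$v, grads)
  params <- tree_map2(function(p, v) p - lr * v, params, state$v)
  list(params = params, state = state)
}
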