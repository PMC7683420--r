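# Layer primitives for the 1-D CNNs. Activations flow as:
#   head stage: N x Ch sample matrix (selection or attention gate)
#   conv stage: (channels, length, batch) arrays; conv uses im2col + BLAS
#   dense stage: (units, batch) matrices
# Each layer_*_forward returns list(out, cache); each *_backward returns
# list(dx, grads) with grads named like the layer's parameters.

#' Rectified linear unit
#'
#' `max(a, 0)`, elementwise: the activation that turns the selection-layer
#' weights into nonnegative importance scores.
#' @param a numeric scalar or array.
#' @export
relu <- function(a) {
  check_finite(a, "relu input")
  pmax(a, 0)
}

glorot_uniform <- function(n_out, n_in, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

# elu(x) = pmax(x, exp(pmin(x, 0)) - 1): exp(x) - 1 >= x for x <= 0, and
# the positive branch stays exactly x. The derivative is exp(pmin(x, 0)).
elu_fwd <- function(x) {
  e <- exp(pmin(x, 0))
  list(y = pmax(x, e - 1), e = e)
}
elu_bwd <- function(dy, e) dy * e

sigmoid <- function(x) 1 / (1 + exp(-x))

att_activation <- function(name) {
  switch(name,
    tanh = list(f = tanh, df = function(y) 1 - y^2),
    sigmoid = list(f = sigmoid, df = function(y) y * (1 - y)),
    identity = list(f = identity, df = function(y) rep(1, length(y))),
    abort_validation("unknown attention activation '", name, "'"))
}

# ---- selection layer (SL block) ----------------------------------------

#' Selection-layer state
#'
#' The per-channel trainable weight vector of the embedded feature
#' selector. Weights start at all ones so the initial score vector
#' `relu(weights)` is uniform and the block is the identity map.
#' @param ch number of spectral channels.
#' @export
sl_state <- function(ch) {
  structure(list(weights = rep(1, as.integer(ch))),
            class = "selection_layer_state")
}

#' Forward pass of the selection block
#'
#' `Y = relu(weights) * X`, the nonnegative score vector broadcast across
#' the batch. With the all-ones initialization this is the identity.
#'
#' @param state a [sl_state()] (or any list with a `weights` vector).
#' @param X numeric N x Ch batch matrix.
#' @return N x Ch weighted batch.
#' @export
sl_forward <- function(state, X) {
  w <- state$weights
  X <- as.matrix(X)
  if (ncol(X) != length(w))
    abort_validation("X has ", ncol(X), " channels; selection layer has ",
                     length(w))
  sweep(X, 2L, relu(w), "*")
}

sl_fwd_cache <- function(layer, X) {
  s <- pmax(layer$weights, 0)
  list(out = sweep(X, 2L, s, "*"), cache = list(X = X, s = s))
}
sl_bwd <- function(layer, dY, cache) {
  dw <- colSums(dY * cache$X) * (layer$weights > 0)
  list(dx = sweep(dY, 2L, cache$s, "*"), grads = list(weights = dw))
}

# ---- attention block (ATT block) ---------------------------------------

#' Attention-block state
#'
#' Two dense layers encode each input spectrum into a per-channel gate:
#' `score = f2(W2 f1(W1 x + b1) + b2)`, and the gated spectrum is
#' `score * x`. The second layer's width equals the channel count so the
#' gate matches the input dimension. Unlike the selection layer the score
#' depends on the sample, so it gates the classifier but is not a channel
#' ranking.
#'
#' @param ch input channel count.
#' @param nn_units width of the first (bottleneck) dense layer.
#' @param f1,f2 activation names (`"tanh"`, `"sigmoid"`, `"identity"`).
#' @export
att_state <- function(ch, nn_units, f1 = "tanh", f2 = "sigmoid") {
  ch <- as.integer(ch); nn_units <- as.integer(nn_units)
  if (nn_units < 1L) abort_validation("nn_units must be >= 1")
  structure(list(
    W1 = glorot_uniform(nn_units, ch, ch, nn_units), b1 = rep(0, nn_units),
    W2 = glorot_uniform(ch, nn_units, nn_units, ch), b2 = rep(0, ch),
    f1 = f1, f2 = f2), class = "attention_block_state")
}

#' Forward pass of the attention block
#'
#' @param state an [att_state()].
#' @param X numeric N x Ch batch matrix.
#' @return list with `Y` (gated batch, N x Ch) and `score` (the
#'   sample-dependent attention scores, N x Ch).
#' @export
att_forward <- function(state, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(state$W1))
    abort_validation("X has ", ncol(X), " channels; attention block expects ",
                     ncol(state$W1))
  a1 <- att_activation(state$f1); a2 <- att_activation(state$f2)
  H <- a1$f(X %*% t(state$W1) + rep(state$b1, each = nrow(X)))
  S <- a2$f(H %*% t(state$W2) + rep(state$b2, each = nrow(X)))
  list(Y = S * X, score = S)
}

att_fwd_cache <- function(layer, X) {
  a1 <- att_activation(layer$f1); a2 <- att_activation(layer$f2)
  H <- a1$f(X %*% t(layer$W1) + rep(layer$b1, each = nrow(X)))
  S <- a2$f(H %*% t(layer$W2) + rep(layer$b2, each = nrow(X)))
  list(out = S * X, cache = list(X = X, H = H, S = S))
}
att_bwd <- function(layer, dY, cache) {
  a1 <- att_activation(layer$f1); a2 <- att_activation(layer$f2)
  X <- cache$X; H <- cache$H; S <- cache$S
  dS <- dY * X
  dZ2 <- dS * a2$df(S)
  dW2 <- t(dZ2) %*% H
  db2 <- colSums(dZ2)
  dH <- dZ2 %*% layer$W2
  dZ1 <- dH * a1$df(H)
  dW1 <- t(dZ1) %*% X
  db1 <- colSums(dZ1)
  dX <- dY * S + dZ1 %*% layer$W1
  list(dx = dX, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# ---- conv stage ---------------------------------------------------------

# im2col linear-index table, memoized per (L, N) in the layer's own env
conv_index <- function(layer, L, N) {
  key <- paste(L, N)
  if (!is.null(layer$idxenv[[key]])) return(layer$idxenv[[key]])
  cin <- layer$cin; ks <- layer$ks; p <- layer$pad
  Lp <- L + 2L * p
  offset <- as.vector(outer(seq_len(cin), (0:(ks - 1L)) * cin, "+"))
  colstart <- as.vector(outer((0:(L - 1L)) * cin,
                              (0:(N - 1L)) * cin * Lp, "+"))
  full <- outer(offset, colstart, "+")
  layer$idxenv[[key]] <- full
  full
}

conv_fwd <- function(layer, A, ...) {
  d <- dim(A); cin <- d[1L]; L <- d[2L]; N <- d[3L]
  p <- layer$pad
  Ap <- array(0, c(cin, L + 2L * p, N))
  Ap[, (p + 1L):(p + L), ] <- A
  P <- Ap[conv_index(layer, L, N)]
  dim(P) <- c(cin * layer$ks, L * N)
  Z <- layer$W %*% P + layer$b
  dim(Z) <- c(layer$cout, L, N)
  list(out = Z, cache = list(P = P, L = L, N = N))
}
conv_bwd <- function(layer, dZ, cache) {
  L <- cache$L; N <- cache$N
  cin <- layer$cin; ks <- layer$ks; p <- layer$pad
  dZm <- dZ
  dim(dZm) <- c(layer$cout, L * N)
  dW <- tcrossprod(dZm, cache$P)
  db <- rowSums(dZm)
  dP <- crossprod(layer$W, dZm)
  dPa <- dP
  dim(dPa) <- c(cin, ks, L, N)
  dAp <- array(0, c(cin, L + 2L * p, N))
  for (kk in seq_len(ks))
    dAp[, kk:(L + kk - 1L), ] <- dAp[, kk:(L + kk - 1L), ] + dPa[, kk, , ]
  list(dx = dAp[, (p + 1L):(p + L), , drop = FALSE],
       grads = list(W = dW, b = db))
}

bn_fwd <- function(layer, A, training) {
  d <- dim(A)
  M <- A
  dim(M) <- c(d[1L], d[2L] * d[3L])
  if (training) {
    mu <- rowMeans(M)
    v <- rowMeans(M * M) - mu^2
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- (M - mu) * invstd
  out <- layer$gamma * xhat + layer$beta
  dim(out) <- d
  list(out = out,
       cache = list(xhat = xhat, invstd = invstd, d = d,
                    mu = mu, v = v, training = training))
}
bn_bwd <- function(layer, dY, cache) {
  d <- cache$d
  dYm <- dY
  dim(dYm) <- c(d[1L], d[2L] * d[3L])
  xhat <- cache$xhat
  dgamma <- rowSums(dYm * xhat)
  dbeta <- rowSums(dYm)
  dxhat <- dYm * layer$gamma
  dx <- cache$invstd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

pool_fwd <- function(layer, A, ...) {
  d <- dim(A); L <- d[2L]; Lout <- L %/% 2L
  odd <- seq(1L, 2L * Lout, by = 2L)
  a <- A[, odd, , drop = FALSE]
  b <- A[, odd + 1L, , drop = FALSE]
  mask <- a >= b
  list(out = pmax(a, b), cache = list(mask = mask, L = L, d = d))
}
pool_bwd <- function(layer, dY, cache) {
  d <- cache$d; Lout <- dim(dY)[2L]
  dA <- array(0, d)
  odd <- seq(1L, 2L * Lout, by = 2L)
  dA[, odd, ] <- dY * cache$mask
  dA[, odd + 1L, ] <- dY * !cache$mask
  list(dx = dA, grads = NULL)
}

# forward/backward dispatch ------------------------------------------------

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    sl = sl_fwd_cache(layer, x),
    att = att_fwd_cache(layer, x),
    reshape = {
      ch <- ncol(x); n <- nrow(x)
      a <- t(x); dim(a) <- c(1L, ch, n)
      list(out = a, cache = list(ch = ch, n = n))
    },
    conv = conv_fwd(layer, x),
    bn = bn_fwd(layer, x, training),
    elu = {
      f <- elu_fwd(x)
      list(out = f$y, cache = list(e = f$e))
    },
    pool = pool_fwd(layer, x),
    flatten = {
      d <- dim(x)
      m <- x; dim(m) <- c(d[1L] * d[2L], d[3L])
      list(out = m, cache = list(d = d))
    },
    dense = list(out = layer$W %*% x + layer$b, cache = list(A = x)),
    abort_validation("unknown layer type ", layer$type))
}

layer_backward <- function(layer, dy, cache) {
  switch(layer$type,
    sl = sl_bwd(layer, dy, cache),
    att = att_bwd(layer, dy, cache),
    reshape = {
      dx <- matrix(dy, cache$ch, cache$n)
      list(dx = t(dx), grads = NULL)
    },
    conv = conv_bwd(layer, dy, cache),
    bn = bn_bwd(layer, dy, cache),
    elu = list(dx = elu_bwd(dy, cache$e), grads = NULL),
    pool = pool_bwd(layer, dy, cache),
    flatten = {
      dx <- dy; dim(dx) <- cache$d
      list(dx = dx, grads = NULL)
    },
    dense = list(dx = crossprod(layer$W, dy),
                 grads = list(W = tcrossprod(dy, cache$A),
                              b = rowSums(dy))),
    abort_validation("unknown layer type ", layer$type))
}

softmax_cols <- function(Z) {
  m <- apply(Z, 2L, max)
  E <- exp(Z - rep(m, each = nrow(Z)))
  E / rep(colSums(E), each = nrow(Z))
}
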