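# Minimal vectorized neural-network primitives (forward + backward) used
# by the two classifiers. Arrays are batch-first: N x T x C for sequences,
# N x D for feature matrices. All heavy lifting is BLAS matrix products.

SELU_LAMBDA <- 1.0507009873554804934193349852946
SELU_ALPHA <- 1.6732632423543772848170429916717

#' Scaled exponential linear unit
#'
#' `selu(x) = lambda * x` for `x > 0` and `lambda * alpha * (exp(x) - 1)`
#' otherwise, with the standard self-normalizing constants
#' lambda ~ 1.05070, alpha ~ 1.67326.
#'
#' @param x Numeric vector/array.
#' @return Same shape as `x`.
#' @export
selu <- function(x) {
  cpp_selu(x)
}

selu_backward <- function(x, dy) {
  cpp_selu_backward(x, dy)
}

# LeCun-normal initialisation (the standard pairing with SELU).
init_weight <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(1 / fan_in)), dim = dims)
}

## ---- 1D convolution (valid padding) ------------------------------------
## im2col + GEMM, implemented in C++ (src/nn_ops.cpp) — this is the hot
## loop of ConvNet training.

# X: N x T x Cin, W: K x Cin x F, b: length F -> Y: N x (T-K+1) x F
conv1d_forward <- function(X, W, b) {
  out <- cpp_conv1d_forward(X, W, b)
  list(Y = out$Y, cache = list(Xcol = out$Xcol, dims = out$dims))
}

conv1d_backward <- function(dY, W, cache) {
  cpp_conv1d_backward(dY, W, cache$Xcol, cache$dims)
}

## ---- max pooling, window 2, stride 2 -----------------------------------

maxpool2_forward <- function(X) {
  out <- cpp_maxpool2_forward(X)
  list(Y = out$Y, cache = list(mask = out$mask, dims = out$dims))
}

maxpool2_backward <- function(dY, cache) {
  cpp_maxpool2_backward(dY, cache$mask, cache$dims)
}

## ---- dense -------------------------------------------------------------

dense_forward <- function(X, W, b) {
  Y <- X %*% W
  sweep(Y, 2, b, `+`)
}

dense_backward <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

## ---- dropout (inverted) ------------------------------------------------

dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0)
    return(list(Y = X, mask = NULL))
  keep <- 1 - rate
  mask <- array((stats::runif(length(X)) < keep) / keep, dim = dim(X) %||%
                  length(X))
  list(Y = X * mask, mask = mask)
}

dropout_backward <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

## ---- softmax cross-entropy ---------------------------------------------

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# labels: integer 0..(n_classes-1); optional per-sample weights.
xent_loss_grad <- function(logits, labels, sample_weights = NULL) {
  n <- nrow(logits)
  probs <- softmax_probs(logits)
  idx <- cbind(seq_len(n), labels + 1L)
  w <- if (is.null(sample_weights)) rep(1, n) else sample_weights
  w <- w / sum(w) # normalise so loss is a weighted mean
  loss <- -sum(w * log(pmax(probs[idx], 1e-12)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits * w
  list(loss = loss, dlogits = dlogits, probs = probs)
}

## ---- layer normalization (over the feature axis) -----------------------

# X: M x D matrix (rows are tokens); gamma, beta length D.
layernorm_forward <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  istd <- 1 / sqrt(v + eps)
  Xhat <- Xc * istd
  Y <- sweep(Xhat, 2, gamma, `*`)
  Y <- sweep(Y, 2, beta, `+`)
  list(Y = Y, cache = list(Xhat = Xhat, istd = istd, gamma = gamma))
}

layernorm_backward <- function(dY, cache) {
  Xhat <- cache$Xhat
  istd <- cache$istd
  D <- ncol(Xhat)
  dgamma <- colSums(dY * Xhat)
  dbeta <- colSums(dY)
  dXhat <- sweep(dY, 2, cache$gamma, `*`)
  # standard layernorm gradient
  dX <- istd * (dXhat - rowMeans(dXhat) - Xhat * rowMeans(dXhat * Xhat))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## ---- multi-head self-attention ------------------------------------------

# X: B x S x D (B sequences of S tokens). Wq/Wk/Wv: D x (H*dk), Wo:
# (H*dk) x D. Loops over sequences and heads; the S x S attention maps
# are cached for the backward pass.
mha_forward <- function(X, Wq, Wk, Wv, Wo, n_heads, key_dim) {
  d <- dim(X)
  B <- d[1]; S <- d[2]; D <- d[3]
  H <- n_heads; dk <- key_dim
  Xmat <- matrix(aperm(X, c(2, 1, 3)), B * S, D) # rows: token s fastest
  Q <- Xmat %*% Wq
  K <- Xmat %*% Wk
  V <- Xmat %*% Wv
  A <- array(0, dim = c(B, H, S, S))
  ctx <- matrix(0, B * S, H * dk)
  scale <- 1 / sqrt(dk)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * S + 1L):(b * S)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      sc <- (Q[rows, cols, drop = FALSE] %*%
               t(K[rows, cols, drop = FALSE])) * scale
      sc <- sc - apply(sc, 1, max)
      e <- exp(sc)
      a <- e / rowSums(e)
      A[b, h, , ] <- a
      ctx[rows, cols] <- a %*% V[rows, cols, drop = FALSE]
    }
  }
  Ymat <- ctx %*% Wo
  Y <- aperm(array(Ymat, dim = c(S, B, D)), c(2, 1, 3))
  list(Y = Y,
       cache = list(Xmat = Xmat, Q = Q, K = K, V = V, A = A, ctx = ctx,
                    dims = c(B, S, D, H, dk)))
}

mha_backward <- function(dY, Wq, Wk, Wv, Wo, cache) {
  dm <- cache$dims
  B <- dm[1]; S <- dm[2]; D <- dm[3]; H <- dm[4]; dk <- dm[5]
  scale <- 1 / sqrt(dk)
  dYmat <- matrix(aperm(dY, c(2, 1, 3)), B * S, D)
  dWo <- crossprod(cache$ctx, dYmat)
  dctx <- dYmat %*% t(Wo)
  dQ <- matrix(0, B * S, H * dk)
  dK <- matrix(0, B * S, H * dk)
  dV <- matrix(0, B * S, H * dk)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * S + 1L):(b * S)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      a <- matrix(cache$A[b, h, , ], S, S)
      dctx_bh <- dctx[rows, cols, drop = FALSE]
      dV[rows, cols] <- crossprod(a, dctx_bh)
      da <- dctx_bh %*% t(cache$V[rows, cols, drop = FALSE])
      # softmax backward, rowwise
      dsc <- a * (da - rowSums(da * a))
      dQ[rows, cols] <- (dsc %*% cache$K[rows, cols, drop = FALSE]) * scale
      dK[rows, cols] <- (crossprod(dsc, cache$Q[rows, cols, drop = FALSE])) *
        scale
    }
  }
  dXmat <- dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv)
  dWq <- crossprod(cache$Xmat, dQ)
  dWk <- crossprod(cache$Xmat, dK)
  dWv <- crossprod(cache$Xmat, dV)
  dX <- aperm(array(dXmat, dim = c(S, B, D)), c(2, 1, 3))
  list(dX = dX, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo)
}

## ---- Nadam optimizer -----------------------------------------------------

nadam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Nadam step over a flat named list of parameter arrays.
nadam_step <- function(params, grads, state, lr, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    # Nesterov lookahead on the first moment
    upd <- (beta1 * mhat + (1 - beta1) * g / (1 - beta1^t)) /
      (sqrt(vhat) + eps)
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

# elementwise accumulate for flat grad lists
grad_accumulate <- function(total, inc) {
  if (is.null(total)) return(inc)
  for (nm in names(inc)) total[[nm]] <- total[[nm]] + inc[[nm]]
  total
}
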