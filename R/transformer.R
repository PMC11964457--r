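#' Time-spatial transformer configuration
#'
#' A two-stage attention classifier: each of the 18 VGRF channels is
#' embedded (scalar -> `d_model` per time step) and passed through a
#' shared *time encoder* (layer-norm, multi-head self-attention over the
#' 100 time steps, dropout, residual, layer-norm, position-wise
#' feed-forward, residual); temporal average pooling yields one embedding
#' per channel. The 18 channel embeddings, with a sinusoidal positional
#' encoding on the sensor index, form the token sequence of a *spatial
#' encoder* with the identical block structure; mean pooling over the 18
#' tokens followed by two dense layers produces the 4-class softmax.
#'
#' @param num_blocks Encoder blocks in each stage (default 1).
#' @param key_dim Per-head query/key/value dimension (default 100).
#' @param num_heads Attention heads (default 2).
#' @param dropout_rate Dropout after attention (default 0.3).
#' @param learning_rate Optimizer learning rate (default 0.01).
#' @param batch_size Minibatch size (default 100).
#' @param d_model Token embedding width (default 16).
#' @param ff_mult Feed-forward width as a multiple of `d_model`.
#' @param fc Sizes of the two head dense layers.
#' @param n_classes Number of classes.
#' @param input_length Segment length in time steps.
#' @param positional_encoding Add the sensor-index positional encoding in
#'   the spatial stage (default `TRUE`). With it off the classifier is
#'   invariant to sensor order.
#' @return An object of class `transformer_config`.
#' @export
transformer_config <- function(num_blocks = 1, key_dim = 100,
                               num_heads = 2, dropout_rate = 0.3,
                               learning_rate = 0.01, batch_size = 100,
                               d_model = 16, ff_mult = 2,
                               fc = c(100, 20), n_classes = 4,
                               input_length = 100,
                               positional_encoding = TRUE) {
  stopifnot(num_blocks >= 1, key_dim >= 1, num_heads >= 1,
            dropout_rate >= 0, dropout_rate < 1, learning_rate > 0,
            batch_size >= 1, d_model >= 2, length(fc) == 2)
  structure(as.list(environment()), class = "transformer_config")
}

# Sinusoidal positional encoding, n_pos x d.
sinusoidal_encoding <- function(n_pos, d) {
  P <- matrix(0, n_pos, d)
  pos <- seq_len(n_pos) - 1
  for (i in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^(2 * (i - 1) / d)
    P[, 2 * i - 1] <- sin(pos * freq)
    if (2 * i <= d) P[, 2 * i] <- cos(pos * freq)
  }
  P
}

encoder_param_names <- function(pfx) {
  paste0(pfx, c("ln1_g", "ln1_b", "Wq", "Wk", "Wv", "Wo",
                "ln2_g", "ln2_b", "ff1_W", "ff1_b", "ff2_W", "ff2_b"))
}

init_encoder_params <- function(cfg) {
  D <- cfg$d_model
  hd <- cfg$num_heads * cfg$key_dim
  ff <- cfg$ff_mult * D
  list(ln1_g = rep(1, D), ln1_b = rep(0, D),
       Wq = init_weight(c(D, hd), D), Wk = init_weight(c(D, hd), D),
       Wv = init_weight(c(D, hd), D), Wo = init_weight(c(hd, D), hd),
       ln2_g = rep(1, D), ln2_b = rep(0, D),
       ff1_W = init_weight(c(D, ff), D), ff1_b = rep(0, ff),
       ff2_W = init_weight(c(ff, D), ff), ff2_b = rep(0, D))
}

#' Build a time-spatial transformer classifier
#'
#' @param config A [transformer_config()].
#' @param n_channels Number of input channels (spatial tokens).
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `c("time_spatial_transformer",
#'   "gait_classifier")`.
#' @export
build_time_spatial_transformer <- function(config = transformer_config(),
                                           n_channels = 18, seed = 1) {
  set.seed(seed)
  D <- config$d_model
  params <- list(embed_W = init_weight(c(1, D), 1), embed_b = rep(0, D))
  for (i in seq_len(config$num_blocks)) {
    tp <- init_encoder_params(config)
    names(tp) <- encoder_param_names(sprintf("t%d_", i))
    sp <- init_encoder_params(config)
    names(sp) <- encoder_param_names(sprintf("s%d_", i))
    params <- c(params, tp, sp)
  }
  params$fc1_W <- init_weight(c(D, config$fc[1]), D)
  params$fc1_b <- rep(0, config$fc[1])
  params$fc2_W <- init_weight(c(config$fc[1], config$fc[2]), config$fc[1])
  params$fc2_b <- rep(0, config$fc[2])
  params$out_W <- init_weight(c(config$fc[2], config$n_classes),
                              config$fc[2])
  params$out_b <- rep(0, config$n_classes)
  structure(list(config = config, n_channels = n_channels,
                 params = params,
                 pos_encoding = sinusoidal_encoding(n_channels, D)),
            class = c("time_spatial_transformer", "gait_classifier"))
}

#' @export
print.time_spatial_transformer <- function(x, ...) {
  cat(sprintf(
    "<time_spatial_transformer> %d channels, %d blocks, %d heads, %d parameters\n",
    x$n_channels, x$config$num_blocks, x$config$num_heads,
    n_parameters(x)))
  invisible(x)
}

as_token_matrix <- function(Xa) {
  d <- dim(Xa)
  matrix(Xa, d[1] * d[2], d[3])
}

as_token_array <- function(M, B, S) {
  array(M, dim = c(B, S, ncol(M)))
}

# One encoder block: x + drop(MHA(ln1(x))), then h + FFN(ln2(h)).
encoder_forward <- function(Xa, p, pfx, cfg, training) {
  d <- dim(Xa)
  B <- d[1]; S <- d[2]
  g <- function(nm) p[[paste0(pfx, nm)]]
  ln1 <- layernorm_forward(as_token_matrix(Xa), g("ln1_g"), g("ln1_b"))
  at <- mha_forward(as_token_array(ln1$Y, B, S), g("Wq"), g("Wk"),
                    g("Wv"), g("Wo"), cfg$num_heads, cfg$key_dim)
  dr <- dropout_forward(at$Y, cfg$dropout_rate, training)
  h <- Xa + dr$Y
  ln2 <- layernorm_forward(as_token_matrix(h), g("ln2_g"), g("ln2_b"))
  z1 <- dense_forward(ln2$Y, g("ff1_W"), g("ff1_b"))
  a1 <- selu(z1)
  z2 <- dense_forward(a1, g("ff2_W"), g("ff2_b"))
  out <- h + as_token_array(z2, B, S)
  list(Y = out,
       cache = list(ln1 = ln1$cache, at = at$cache, dr = dr, ln2 = ln2$cache,
                    ln2_out = ln2$Y, z1 = z1, a1 = a1, h = h, B = B, S = S))
}

encoder_backward <- function(dY, cc, p, pfx) {
  g <- function(nm) p[[paste0(pfx, nm)]]
  grads <- list()
  B <- cc$B; S <- cc$S
  dmat <- as_token_matrix(dY)
  # FFN path
  b2 <- dense_backward(dmat, cc$a1, g("ff2_W"))
  grads[[paste0(pfx, "ff2_W")]] <- b2$dW
  grads[[paste0(pfx, "ff2_b")]] <- b2$db
  dz1 <- selu_backward(cc$z1, b2$dX)
  b1 <- dense_backward(dz1, cc$ln2_out, g("ff1_W"))
  grads[[paste0(pfx, "ff1_W")]] <- b1$dW
  grads[[paste0(pfx, "ff1_b")]] <- b1$db
  ln2b <- layernorm_backward(b1$dX, cc$ln2)
  grads[[paste0(pfx, "ln2_g")]] <- ln2b$dgamma
  grads[[paste0(pfx, "ln2_b")]] <- ln2b$dbeta
  dh <- dmat + ln2b$dX # residual + FFN input path
  dh_arr <- as_token_array(dh, B, S)
  # attention path
  dat <- dropout_backward(dh_arr, cc$dr$mask)
  mb <- mha_backward(dat, g("Wq"), g("Wk"), g("Wv"), g("Wo"), cc$at)
  grads[[paste0(pfx, "Wq")]] <- mb$dWq
  grads[[paste0(pfx, "Wk")]] <- mb$dWk
  grads[[paste0(pfx, "Wv")]] <- mb$dWv
  grads[[paste0(pfx, "Wo")]] <- mb$dWo
  ln1b <- layernorm_backward(as_token_matrix(mb$dX), cc$ln1)
  grads[[paste0(pfx, "ln1_g")]] <- ln1b$dgamma
  grads[[paste0(pfx, "ln1_b")]] <- ln1b$dbeta
  dX <- dh_arr + as_token_array(ln1b$dX, B, S)
  list(dX = dX, grads = grads)
}

#' @export
nn_forward.time_spatial_transformer <- function(model, X, training = FALSE) {
  cfg <- model$config
  p <- model$params
  d <- dim(X)
  N <- d[1]; S <- d[2]; C <- d[3]
  if (S != cfg$input_length)
    stop("input length ", S, " != expected ", cfg$input_length)
  if (C != model$n_channels)
    stop("input has ", C, " channels; model expects ", model$n_channels)
  X <- apply_channel_norm(model, X)
  B <- N * C
  # sequences: one per (segment, channel); b = n + (c-1)*N
  Xseq <- matrix(aperm(X, c(1, 3, 2)), B, S)
  Emat <- matrix(as.vector(Xseq), B * S, 1) %*% p$embed_W
  Emat <- sweep(Emat, 2, p$embed_b, `+`)
  E <- as_token_array(Emat, B, S)
  tcaches <- vector("list", cfg$num_blocks)
  for (i in seq_len(cfg$num_blocks)) {
    ef <- encoder_forward(E, p, sprintf("t%d_", i), cfg, training)
    E <- ef$Y
    tcaches[[i]] <- ef$cache
  }
  # temporal mean pooling -> one embedding per (segment, channel)
  D <- cfg$d_model
  Z <- matrix(0, B, D)
  for (j in seq_len(D)) Z[, j] <- rowMeans(E[, , j])
  Tsp <- array(Z, dim = c(N, C, D))
  if (cfg$positional_encoding) {
    for (c in seq_len(C))
      Tsp[, c, ] <- Tsp[, c, ] +
        matrix(model$pos_encoding[c, ], N, D, byrow = TRUE)
  }
  scaches <- vector("list", cfg$num_blocks)
  Ssp <- Tsp
  for (i in seq_len(cfg$num_blocks)) {
    ef <- encoder_forward(Ssp, p, sprintf("s%d_", i), cfg, training)
    Ssp <- ef$Y
    scaches[[i]] <- ef$cache
  }
  # mean pooling over the C sensor tokens
  pool <- matrix(0, N, D)
  for (j in seq_len(D)) pool[, j] <- rowMeans(Ssp[, , j])
  z1 <- dense_forward(pool, p$fc1_W, p$fc1_b)
  a1 <- selu(z1)
  z2 <- dense_forward(a1, p$fc2_W, p$fc2_b)
  a2 <- selu(z2)
  logits <- dense_forward(a2, p$out_W, p$out_b)
  list(logits = logits,
       cache = list(Xseq = Xseq, tcaches = tcaches, scaches = scaches,
                    pool = pool, z1 = z1, a1 = a1, z2 = z2, a2 = a2,
                    N = N, S = S, C = C, B = B),
       n_spatial_tokens = C)
}

#' @export
nn_backward.time_spatial_transformer <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  N <- cache$N; S <- cache$S; C <- cache$C; B <- cache$B
  D <- cfg$d_model
  g <- list()
  bo <- dense_backward(dlogits, cache$a2, p$out_W)
  g$out_W <- bo$dW; g$out_b <- bo$db
  dz2 <- selu_backward(cache$z2, bo$dX)
  b2 <- dense_backward(dz2, cache$a1, p$fc2_W)
  g$fc2_W <- b2$dW; g$fc2_b <- b2$db
  dz1 <- selu_backward(cache$z1, b2$dX)
  b1 <- dense_backward(dz1, cache$pool, p$fc1_W)
  g$fc1_W <- b1$dW; g$fc1_b <- b1$db
  # un-pool over sensor tokens
  dS <- array(0, dim = c(N, C, D))
  for (j in seq_len(D)) dS[, , j] <- b1$dX[, j] / C
  for (i in rev(seq_len(cfg$num_blocks))) {
    eb <- encoder_backward(dS, cache$scaches[[i]], p, sprintf("s%d_", i))
    dS <- eb$dX
    g <- c(g, eb$grads)
  }
  # positional encoding is fixed; gradient passes straight through
  dZ <- matrix(dS, B, D) # (N, C, D) -> (N*C) x D with b = n + (c-1)N
  # un-pool over time
  dE <- array(0, dim = c(B, S, D))
  for (j in seq_len(D)) dE[, , j] <- dZ[, j] / S
  for (i in rev(seq_len(cfg$num_blocks))) {
    eb <- encoder_backward(dE, cache$tcaches[[i]], p, sprintf("t%d_", i))
    dE <- eb$dX
    g <- c(g, eb$grads)
  }
  dEmat <- as_token_matrix(dE)
  g$embed_W <- crossprod(matrix(as.vector(cache$Xseq), B * S, 1), dEmat)
  g$embed_b <- colSums(dEmat)
  g[names(model$params)]
}
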