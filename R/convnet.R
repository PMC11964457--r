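#' 1D ConvNet configuration
#'
#' Architecture of the per-channel convolutional branch network: each of
#' the 18 input channels is processed by its own branch of four valid
#' convolutions with SELU activations — (8 filters, kernel 3),
#' (16, 3), max-pool 2, (16, 3), (1, 3), max-pool 2 — flattened and
#' projected to a 50-unit embedding; the 18 embeddings are concatenated
#' and fused through two dense layers (100, 20) with dropout before a
#' 4-class softmax.
#'
#' @param conv_specs List of `(filters, kernel)` pairs for the four
#'   convolution layers.
#' @param dense_per_channel Units of the per-branch embedding layer.
#' @param fc Sizes of the two fusion dense layers.
#' @param dropout_rate Dropout after each fusion dense layer.
#' @param learning_rate Optimizer learning rate (default 0.01).
#' @param batch_size Minibatch size (default 200).
#' @param n_classes Number of output classes.
#' @param input_length Segment length in time steps (fixed 100).
#' @param shared_branches If `TRUE`, all channels share one branch's
#'   weights; default `FALSE` (a branch per channel).
#' @return An object of class `convnet_config`.
#' @export
convnet_config <- function(conv_specs = list(c(8, 3), c(16, 3),
                                             c(16, 3), c(1, 3)),
                           dense_per_channel = 50,
                           fc = c(100, 20),
                           dropout_rate = 0.1,
                           learning_rate = 0.01,
                           batch_size = 200,
                           n_classes = 4,
                           input_length = 100,
                           shared_branches = FALSE) {
  stopifnot(length(conv_specs) == 4, length(fc) == 2,
            dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0, batch_size >= 1)
  kernels <- vapply(conv_specs, `[`, 0, 2)
  if (any(kernels %% 2 == 0)) stop("kernel sizes must be odd")
  structure(as.list(environment())[c(
    "conv_specs", "dense_per_channel", "fc", "dropout_rate",
    "learning_rate", "batch_size", "n_classes", "input_length",
    "shared_branches")], class = "convnet_config")
}

# Flattened output length of one branch for a given input length.
branch_flat_length <- function(config) {
  T <- config$input_length
  k <- vapply(config$conv_specs, `[`, 0, 2)
  T <- T - k[1] + 1 # conv1
  T <- T - k[2] + 1 # conv2
  T <- T %/% 2 # pool
  T <- T - k[3] + 1 # conv3
  T <- T - k[4] + 1 # conv4
  T <- T %/% 2 # pool
  T * config$conv_specs[[4]][1]
}

#' Build a per-channel 1D ConvNet classifier
#'
#' Initialises all weights (LeCun normal, seeded) for the architecture
#' described in [convnet_config()].
#'
#' @param config A [convnet_config()].
#' @param n_channels Number of input channels (18 for full VGRF input).
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `c("convnet", "gait_classifier")`.
#' @export
build_convnet <- function(config = convnet_config(), n_channels = 18,
                          seed = 1) {
  set.seed(seed)
  cs <- config$conv_specs
  flat <- branch_flat_length(config)
  n_branches <- if (config$shared_branches) 1L else n_channels
  params <- list()
  for (b in seq_len(n_branches)) {
    pfx <- sprintf("b%02d_", b)
    cin <- 1L
    for (l in 1:4) {
      f <- cs[[l]][1]; k <- cs[[l]][2]
      params[[paste0(pfx, "conv", l, "_W")]] <-
        init_weight(c(k, cin, f), fan_in = k * cin)
      params[[paste0(pfx, "conv", l, "_b")]] <- rep(0, f)
      cin <- f
    }
    params[[paste0(pfx, "dense_W")]] <-
      init_weight(c(flat, config$dense_per_channel), fan_in = flat)
    params[[paste0(pfx, "dense_b")]] <- rep(0, config$dense_per_channel)
  }
  concat <- n_channels * config$dense_per_channel
  params$fc1_W <- init_weight(c(concat, config$fc[1]), fan_in = concat)
  params$fc1_b <- rep(0, config$fc[1])
  params$fc2_W <- init_weight(c(config$fc[1], config$fc[2]),
                              fan_in = config$fc[1])
  params$fc2_b <- rep(0, config$fc[2])
  params$out_W <- init_weight(c(config$fc[2], config$n_classes),
                              fan_in = config$fc[2])
  params$out_b <- rep(0, config$n_classes)
  structure(list(config = config, n_channels = n_channels,
                 params = params),
            class = c("convnet", "gait_classifier"))
}

#' @export
print.convnet <- function(x, ...) {
  cat(sprintf("<convnet> %d channels, %d parameters%s\n", x$n_channels,
              n_parameters(x),
              if (x$config$shared_branches) " (shared branches)" else ""))
  invisible(x)
}

#' Total parameter count of a classifier
#' @param model A `gait_classifier`.
#' @return Integer.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 0L))
}

branch_prefix <- function(model, channel) {
  if (model$config$shared_branches) "b01_" else sprintf("b%02d_", channel)
}

# Forward pass. X: N x T x C. Returns logits and a cache for backward.
#' @export
nn_forward.convnet <- function(model, X, training = FALSE) {
  cfg <- model$config
  p <- model$params
  if (dim(X)[2] != cfg$input_length)
    stop("input length ", dim(X)[2], " != expected ", cfg$input_length)
  if (dim(X)[3] != model$n_channels)
    stop("input has ", dim(X)[3], " channels; model expects ",
         model$n_channels)
  X <- apply_channel_norm(model, X)
  N <- dim(X)[1]
  caches <- vector("list", model$n_channels)
  embed <- matrix(0, N, model$n_channels * cfg$dense_per_channel)
  for (c in seq_len(model$n_channels)) {
    pfx <- branch_prefix(model, c)
    h <- array(X[, , c], dim = c(N, cfg$input_length, 1L))
    cc <- list(x0 = h)
    cv1 <- conv1d_forward(h, p[[paste0(pfx, "conv1_W")]],
                          p[[paste0(pfx, "conv1_b")]])
    cc$z1 <- cv1$Y; cc$c1 <- cv1$cache
    cv2 <- conv1d_forward(selu(cv1$Y), p[[paste0(pfx, "conv2_W")]],
                          p[[paste0(pfx, "conv2_b")]])
    cc$z2 <- cv2$Y; cc$c2 <- cv2$cache
    mp1 <- maxpool2_forward(selu(cv2$Y))
    cc$p1 <- mp1$cache
    cv3 <- conv1d_forward(mp1$Y, p[[paste0(pfx, "conv3_W")]],
                          p[[paste0(pfx, "conv3_b")]])
    cc$z3 <- cv3$Y; cc$c3 <- cv3$cache
    cv4 <- conv1d_forward(selu(cv3$Y), p[[paste0(pfx, "conv4_W")]],
                          p[[paste0(pfx, "conv4_b")]])
    cc$z4 <- cv4$Y; cc$c4 <- cv4$cache
    mp2 <- maxpool2_forward(selu(cv4$Y))
    cc$p2 <- mp2$cache
    flat <- matrix(mp2$Y, N) # N x (Tpool*F)
    cc$flat <- flat
    zd <- dense_forward(flat, p[[paste0(pfx, "dense_W")]],
                        p[[paste0(pfx, "dense_b")]])
    cc$zd <- zd
    embed[, ((c - 1) * cfg$dense_per_channel + 1):
              (c * cfg$dense_per_channel)] <- selu(zd)
    caches[[c]] <- cc
  }
  z1 <- dense_forward(embed, p$fc1_W, p$fc1_b)
  a1 <- selu(z1)
  d1 <- dropout_forward(a1, cfg$dropout_rate, training)
  z2 <- dense_forward(d1$Y, p$fc2_W, p$fc2_b)
  a2 <- selu(z2)
  d2 <- dropout_forward(a2, cfg$dropout_rate, training)
  logits <- dense_forward(d2$Y, p$out_W, p$out_b)
  list(logits = logits,
       cache = list(branches = caches, embed = embed, z1 = z1, d1 = d1,
                    z2 = z2, d2 = d2))
}

#' @export
nn_backward.convnet <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  g <- list()
  bo <- dense_backward(dlogits, cache$d2$Y, p$out_W)
  g$out_W <- bo$dW; g$out_b <- bo$db
  da2 <- dropout_backward(bo$dX, cache$d2$mask)
  dz2 <- selu_backward(cache$z2, da2)
  b2 <- dense_backward(dz2, cache$d1$Y, p$fc2_W)
  g$fc2_W <- b2$dW; g$fc2_b <- b2$db
  da1 <- dropout_backward(b2$dX, cache$d1$mask)
  dz1 <- selu_backward(cache$z1, da1)
  b1 <- dense_backward(dz1, cache$embed, p$fc1_W)
  g$fc1_W <- b1$dW; g$fc1_b <- b1$db
  dembed <- b1$dX
  for (c in seq_len(model$n_channels)) {
    pfx <- branch_prefix(model, c)
    cc <- cache$branches[[c]]
    dcols <- ((c - 1) * cfg$dense_per_channel + 1):
      (c * cfg$dense_per_channel)
    dzd <- selu_backward(cc$zd, dembed[, dcols, drop = FALSE])
    bd <- dense_backward(dzd, cc$flat, p[[paste0(pfx, "dense_W")]])
    g[[paste0(pfx, "dense_W")]] <-
      (g[[paste0(pfx, "dense_W")]] %||% 0) + bd$dW
    g[[paste0(pfx, "dense_b")]] <-
      (g[[paste0(pfx, "dense_b")]] %||% 0) + bd$db
    dflat <- bd$dX
    dim(dflat) <- dim_from_cache(cc$p2)
    dp2 <- maxpool2_backward_from_flat(dflat, cc$p2)
    dz4 <- selu_backward(cc$z4, dp2)
    b4 <- conv1d_backward(dz4, p[[paste0(pfx, "conv4_W")]], cc$c4)
    g[[paste0(pfx, "conv4_W")]] <-
      (g[[paste0(pfx, "conv4_W")]] %||% 0) + b4$dW
    g[[paste0(pfx, "conv4_b")]] <-
      (g[[paste0(pfx, "conv4_b")]] %||% 0) + b4$db
    dz3 <- selu_backward(cc$z3, b4$dX)
    b3 <- conv1d_backward(dz3, p[[paste0(pfx, "conv3_W")]], cc$c3)
    g[[paste0(pfx, "conv3_W")]] <-
      (g[[paste0(pfx, "conv3_W")]] %||% 0) + b3$dW
    g[[paste0(pfx, "conv3_b")]] <-
      (g[[paste0(pfx, "conv3_b")]] %||% 0) + b3$db
    dp1 <- maxpool2_backward(b3$dX, cc$p1)
    dz2c <- selu_backward(cc$z2, dp1)
    b2c <- conv1d_backward(dz2c, p[[paste0(pfx, "conv2_W")]], cc$c2)
    g[[paste0(pfx, "conv2_W")]] <-
      (g[[paste0(pfx, "conv2_W")]] %||% 0) + b2c$dW
    g[[paste0(pfx, "conv2_b")]] <-
      (g[[paste0(pfx, "conv2_b")]] %||% 0) + b2c$db
    dz1c <- selu_backward(cc$z1, b2c$dX)
    b1c <- conv1d_backward(dz1c, p[[paste0(pfx, "conv1_W")]], cc$c1)
    g[[paste0(pfx, "conv1_W")]] <-
      (g[[paste0(pfx, "conv1_W")]] %||% 0) + b1c$dW
    g[[paste0(pfx, "conv1_b")]] <-
      (g[[paste0(pfx, "conv1_b")]] %||% 0) + b1c$db
  }
  # ensure every param has a gradient entry, in param order
  g[setdiff(names(model$params), names(g))] <- NULL
  g[names(model$params)]
}

# pooled output dims recorded in the maxpool cache
dim_from_cache <- function(pcache) {
  d <- pcache$dims
  c(d[1], d[2] %/% 2L, d[3])
}

maxpool2_backward_from_flat <- function(dYarr, pcache) {
  maxpool2_backward(dYarr, pcache)
}
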