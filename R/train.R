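#' @export
nn_forward <- function(model, X, training = FALSE) UseMethod("nn_forward")

#' @export
nn_backward <- function(model, cache, dlogits) UseMethod("nn_backward")

#' Training configuration
#'
#' Nadam optimisation of the categorical cross-entropy with early
#' stopping on validation loss: training halts once the monitored loss
#' has failed to improve by at least `min_delta` for `patience` epochs,
#' and the best-epoch weights are restored.
#'
#' @param learning_rate Learning rate; `NULL` uses the model config's
#'   value. (0.0002 is a conservative alternative for long runs.)
#' @param beta1,beta2 Nadam moment decay rates (0.9, 0.999).
#' @param epsilon Nadam denominator fuzz.
#' @param max_epochs Epoch cap.
#' @param min_delta Minimum val-loss improvement that resets patience.
#' @param patience Epochs without improvement before stopping.
#' @param batch_size Minibatch size; `NULL` uses the model config's value.
#' @param class_weights Optional length-`n_classes` vector of loss
#'   weights (e.g. inverse class frequencies); default none.
#' @param seed Seed for shuffling, dropout and any augmentation stream.
#' @param verbose Print per-epoch losses.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = NULL, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-7, max_epochs = 100,
                         min_delta = 1e-4, patience = 10,
                         batch_size = NULL, class_weights = NULL,
                         seed = 1, verbose = FALSE) {
  stopifnot(is.null(learning_rate) || learning_rate > 0,
            patience >= 1, max_epochs >= 1, min_delta >= 0)
  structure(as.list(environment()), class = "train_config")
}

batch_xy <- function(batch) {
  if (inherits(batch, "segment_batch"))
    list(X = batch$segments, y = batch$labels)
  else
    list(X = batch$X, y = batch$y)
}

model_loss <- function(model, X, y, weights = NULL, chunk = 512L) {
  n <- dim(X)[1]
  total <- 0
  correct <- 0
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    fw <- nn_forward(model, X[s:e, , , drop = FALSE], training = FALSE)
    lw <- if (is.null(weights)) NULL else weights[y[s:e] + 1L]
    lg <- xent_loss_grad(fw$logits, y[s:e], lw)
    total <- total + lg$loss * (e - s + 1L)
    correct <- correct + sum(max.col(lg$probs) - 1L == y[s:e])
  }
  list(loss = total / n, acc = correct / n)
}

#' Train a classifier
#'
#' Minimises categorical cross-entropy with Nadam, monitoring validation
#' loss for early stopping and restoring the best-epoch weights. Fully
#' seeded; aborts with a diagnostic on divergence (non-finite loss).
#' Subject independence of the two batches is asserted when provenance is
#' available.
#'
#' @param model A `gait_classifier` from [build_convnet()] or
#'   [build_time_spatial_transformer()].
#' @param train_batch,val_batch `segment_batch`es (or lists with `X`,
#'   `y`).
#' @param config A [train_config()].
#' @return The fitted model, with a `history` data.frame (epoch, loss,
#'   val_loss, val_acc) and `best_epoch` attached.
#' @export
train_classifier <- function(model, train_batch, val_batch,
                             config = train_config()) {
  tr <- batch_xy(train_batch)
  va <- batch_xy(val_batch)
  if (!length(tr$y) || !length(va$y)) stop("empty training or validation batch")
  if (inherits(train_batch, "segment_batch") &&
      inherits(val_batch, "segment_batch")) {
    overlap <- intersect(unique(train_batch$provenance$subject_id),
                         unique(val_batch$provenance$subject_id))
    if (length(overlap))
      stop("subject leakage between train and validation: ",
           paste(overlap, collapse = ", "))
  }
  lr <- config$learning_rate %||% model$config$learning_rate
  bs <- config$batch_size %||% model$config$batch_size
  wts <- config$class_weights
  # per-channel z-scoring fitted on the training batch (stored on the
  # model, applied at every forward pass) keeps raw newton-scale inputs
  # well conditioned for the optimizer
  if (is.null(model$norm)) {
    C <- dim(tr$X)[3]
    mu <- vapply(seq_len(C), function(c) mean(tr$X[, , c]), 0)
    sg <- vapply(seq_len(C), function(c) stats::sd(tr$X[, , c]), 0)
    sg[!is.finite(sg) | sg < 1e-8] <- 1
    model$norm <- list(mean = mu, sd = sg)
  }
  set.seed(config$seed)
  state <- nadam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  wait <- 0L
  hist <- data.frame()
  n <- length(tr$y)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (s in seq(1, n, by = bs)) {
      idx <- ord[s:min(n, s + bs - 1L)]
      fw <- nn_forward(model, tr$X[idx, , , drop = FALSE], training = TRUE)
      lw <- if (is.null(wts)) NULL else wts[tr$y[idx] + 1L]
      lg <- xent_loss_grad(fw$logits, tr$y[idx], lw)
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      ep_loss <- ep_loss + lg$loss * length(idx)
      grads <- nn_backward(model, fw$cache, lg$dlogits)
      upd <- nadam_step(model$params, grads, state, lr,
                        config$beta1, config$beta2, config$epsilon)
      model$params <- upd$params
      state <- upd$state
    }
    vl <- model_loss(model, va$X, va$y, wts)
    hist <- rbind(hist, data.frame(epoch = epoch, loss = ep_loss / n,
                                   val_loss = vl$loss, val_acc = vl$acc))
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.4f  val_loss %.4f  val_acc %.3f",
                      epoch, ep_loss / n, vl$loss, vl$acc))
    if (vl$loss < best$loss - config$min_delta) {
      best <- list(loss = vl$loss, params = model$params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model$params <- best$params
  model$history <- hist
  model$best_epoch <- best$epoch
  model
}

#' Predict classes for a batch of segments
#'
#' Deterministic inference: per-segment class probabilities and argmax
#' class indices.
#'
#' @param model A fitted `gait_classifier`.
#' @param batch A `segment_batch` or N×T×C array.
#' @param chunk Segments per forward chunk (memory control).
#' @return List with `class` (integer 0..3) and `probs` (N×4 matrix).
#' @export
predict_segments <- function(model, batch, chunk = 512L) {
  X <- if (inherits(batch, "segment_batch")) batch$segments else batch
  n <- dim(X)[1]
  probs <- matrix(0, n, model$config$n_classes)
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    fw <- nn_forward(model, X[s:e, , , drop = FALSE], training = FALSE)
    probs[s:e, ] <- softmax_probs(fw$logits)
  }
  list(class = max.col(probs, ties.method = "first") - 1L, probs = probs)
}

# Apply the per-channel z-scoring fitted at training time; identity for
# an unfitted model.
apply_channel_norm <- function(model, X) {
  if (is.null(model$norm)) return(X)
  for (c in seq_len(dim(X)[3]))
    X[, , c] <- (X[, , c] - model$norm$mean[c]) / model$norm$sd[c]
  X
}
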