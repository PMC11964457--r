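test_that("selu matches its closed form on a dense grid", {
  lambda <- 1.0507009873554804934193349852946
  alpha <- 1.6732632423543772848170429916717
  x <- seq(-8, 8, length.out = 1000)
  expected <- ifelse(x > 0, lambda * x, lambda * alpha * (exp(x) - 1))
  expect_equal(selu(x), expected, tolerance = 1e-12)
  expect_identical(selu(0), 0)
  expect_equal(selu(1), lambda, tolerance = 1e-12)
  # asymptote as x -> -Inf
  expect_equal(selu(-50), -lambda * alpha, tolerance = 1e-12)
})

test_that("convnet forward pass has the documented geometry", {
  m <- build_convnet(n_channels = 18, seed = 1)
  X <- array(0, c(3, 100, 18))
  fw <- nn_forward(m, X)
  probs <- gaitsev:::softmax_probs(fw$logits)
  expect_equal(dim(probs), c(3, 4))
  expect_equal(rowSums(probs), rep(1, 3))
  expect_true(all(is.finite(fw$logits))) # zero input stays finite
  # per-channel embedding is 50 wide
  expect_equal(ncol(fw$cache$branches[[1]]$zd), 50)
  expect_equal(ncol(fw$cache$embed), 18 * 50)
  expect_error(nn_forward(m, array(0, c(2, 99, 18))), "input length")
  expect_error(nn_forward(m, array(0, c(2, 100, 17))), "channels")
})

test_that("model parameter counts are stable documented constants", {
  expect_equal(n_parameters(build_convnet(n_channels = 18, seed = 1)),
               135674)
  expect_equal(n_parameters(build_convnet(n_channels = 16, seed = 1)),
               120844)
  expect_equal(
    n_parameters(build_time_spatial_transformer(n_channels = 18, seed = 1)),
    31708)
})

test_that("analytic gradients match finite differences (both models)", {
  grad_check <- function(model, X, y, per_param = 2) {
    fw <- nn_forward(model, X)
    lg <- gaitsev:::xent_loss_grad(fw$logits, y)
    g <- nn_backward(model, fw$cache, lg$dlogits)
    eps <- 1e-6
    worst <- 0
    set.seed(17)
    for (nm in names(model$params)) {
      n <- length(model$params[[nm]])
      for (i in sample(n, min(per_param, n))) {
        m2 <- model
        m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
        l1 <- gaitsev:::xent_loss_grad(nn_forward(m2, X)$logits, y)$loss
        m2$params[[nm]][i] <- m2$params[[nm]][i] - 2 * eps
        l0 <- gaitsev:::xent_loss_grad(nn_forward(m2, X)$logits, y)$loss
        num <- (l1 - l0) / (2 * eps)
        worst <- max(worst, abs(num - g[[nm]][i]) /
                       max(1e-6, abs(num) + abs(g[[nm]][i])))
      }
    }
    worst
  }
  set.seed(31)
  X <- array(rnorm(4 * 100 * 3), c(4, 100, 3))
  y <- c(0, 1, 2, 3)
  cn <- build_convnet(convnet_config(dropout_rate = 0), n_channels = 3,
                      seed = 2)
  expect_lt(grad_check(cn, X, y), 1e-4)
  tf <- build_time_spatial_transformer(
    transformer_config(key_dim = 8, d_model = 8, dropout_rate = 0,
                       fc = c(16, 8)), n_channels = 3, seed = 2)
  expect_lt(grad_check(tf, X, y), 1e-3)
})

test_that("the spatial encoder attends over exactly 18 sensor tokens", {
  tf <- build_time_spatial_transformer(n_channels = 18, seed = 1)
  X <- array(rnorm(2 * 100 * 18), c(2, 100, 18))
  fw <- nn_forward(tf, X)
  expect_equal(fw$n_spatial_tokens, 18)
  expect_equal(dim(fw$cache$scaches[[1]]$at$A)[3:4], c(18, 18))
  probs <- gaitsev:::softmax_probs(fw$logits)
  expect_equal(rowSums(probs), rep(1, 2))
})

test_that("sensor order matters exactly when positional encoding is on", {
  tf <- build_time_spatial_transformer(n_channels = 18, seed = 3)
  set.seed(4)
  X <- array(rnorm(2 * 100 * 18), c(2, 100, 18))
  perm <- sample(18)
  p_on_1 <- gaitsev:::softmax_probs(nn_forward(tf, X)$logits)
  p_on_2 <- gaitsev:::softmax_probs(
    nn_forward(tf, X[, , perm, drop = FALSE])$logits)
  expect_gt(max(abs(p_on_1 - p_on_2)), 1e-6)
  tf$config$positional_encoding <- FALSE
  p_off_1 <- gaitsev:::softmax_probs(nn_forward(tf, X)$logits)
  p_off_2 <- gaitsev:::softmax_probs(
    nn_forward(tf, X[, , perm, drop = FALSE])$logits)
  expect_equal(p_off_1, p_off_2, tolerance = 1e-10)
})

test_that("training is deterministic, learns a separable toy, stops early", {
  # two well-separated classes of 1-channel segments
  make_toy <- function(n, seed) {
    set.seed(seed)
    X <- array(rnorm(n * 100 * 2, sd = 0.3), c(n, 100, 2))
    y <- rep(0:1, length.out = n)
    X[y == 1, 40:60, 1] <- X[y == 1, 40:60, 1] + 2
    list(X = X, y = y)
  }
  tr <- make_toy(40, 1)
  va <- make_toy(16, 2)
  cfg <- convnet_config(dropout_rate = 0, batch_size = 20,
                        learning_rate = 0.005)
  m1 <- train_classifier(build_convnet(cfg, n_channels = 2, seed = 5),
                         tr, va,
                         train_config(max_epochs = 8, patience = 8,
                                      seed = 9))
  m2 <- train_classifier(build_convnet(cfg, n_channels = 2, seed = 5),
                         tr, va,
                         train_config(max_epochs = 8, patience = 8,
                                      seed = 9))
  expect_identical(m1$history, m2$history) # bitwise-identical runs
  expect_lt(m1$history$loss[nrow(m1$history)], m1$history$loss[1])
  expect_gt(tail(m1$history$val_acc, 1), 0.9)
  pred <- predict_segments(m1, va$X)
  expect_length(pred$class, 16)
  expect_equal(pred$class, max.col(pred$probs) - 1L)
})

test_that("early stopping triggers after patience epochs without gain", {
  tr <- list(X = array(rnorm(20 * 100 * 1), c(20, 100, 1)),
             y = rep(0:1, 10))
  # validation labels are pure noise: val loss cannot improve for long
  va <- list(X = array(rnorm(20 * 100 * 1), c(20, 100, 1)),
             y = sample(0:1, 20, TRUE))
  m <- train_classifier(
    build_convnet(convnet_config(dropout_rate = 0, batch_size = 20,
                                 learning_rate = 1e-5),
                  n_channels = 1, seed = 1),
    tr, va, train_config(max_epochs = 50, patience = 3, min_delta = 10,
                         seed = 2))
  # epoch 1 sets the baseline; then patience epochs without improvement
  expect_equal(nrow(m$history), 4)
})

test_that("subject leakage between batches aborts training", {
  co <- tiny_cohort(n = 2, duration = 2)
  sb <- segment_batch(co$walks)
  m <- build_convnet(tiny_convnet_config(), n_channels = 18, seed = 1)
  expect_error(train_classifier(m, sb, sb, train_config(max_epochs = 1)),
               "leakage")
})
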