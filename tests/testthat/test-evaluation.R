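# Recount oracle: per-class one-vs-rest metrics from raw (truth, pred)
# pairs.
metrics_oracle <- function(truth, pred, K = 4) {
  per <- lapply(0:(K - 1), function(k) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(support = sum(truth == k), precision = p, recall = r, f1 = f)
  })
  m <- do.call(rbind, per)
  w <- m[, "support"] / length(truth)
  list(per = m,
       weighted = colSums(m[, c("precision", "recall", "f1")] * w),
       accuracy = mean(truth == pred))
}

test_that("metric formulas reproduce the worked binary example", {
  # TP = 3, FP = 1, FN = 1, TN = 2 for the positive class
  cm <- matrix(c(2, 1, 1, 3), 2, 2, byrow = TRUE)
  m <- classification_metrics(cm)
  pos <- 2 # second row/column is the positive class
  expect_equal(m$per_class$precision[pos], 0.75)
  expect_equal(m$per_class$recall[pos], 0.75)
  expect_equal(m$per_class$f1[pos], 0.75)
  expect_equal(m$accuracy, 5 / 7)
})

test_that("metrics equal the recount oracle on random instances", {
  set.seed(40)
  for (i in 1:25) {
    n <- sample(20:1000, 1)
    truth <- sample(0:3, n, TRUE)
    pred <- ifelse(runif(n) < 0.6, truth, sample(0:3, n, TRUE))
    cm <- as.matrix(table(factor(truth, 0:3), factor(pred, 0:3)))
    m <- suppressWarnings(classification_metrics(cm))
    o <- metrics_oracle(truth, pred)
    expect_equal(m$per_class$precision, unname(o$per[, "precision"]),
                 tolerance = 1e-12)
    expect_equal(m$per_class$recall, unname(o$per[, "recall"]),
                 tolerance = 1e-12)
    expect_equal(m$per_class$f1, unname(o$per[, "f1"]), tolerance = 1e-12)
    expect_equal(unname(m$weighted), unname(o$weighted), tolerance = 1e-12)
    expect_equal(m$accuracy, o$accuracy, tolerance = 1e-12)
  }
})

test_that("perfect and degenerate confusion matrices behave as defined", {
  eye <- diag(c(5L, 3L, 2L, 4L))
  m <- classification_metrics(eye)
  expect_equal(m$per_class$precision, rep(1, 4))
  expect_equal(m$per_class$f1, rep(1, 4))
  expect_equal(m$accuracy, 1)
  # equal supports: weighted average equals the plain mean
  cm <- matrix(c(7, 1, 1, 1,
                 1, 7, 1, 1,
                 2, 1, 6, 1,
                 1, 1, 1, 7), 4, 4, byrow = TRUE) # all rows sum to 10
  m2 <- classification_metrics(cm)
  expect_equal(unname(m2$weighted["precision"]),
               mean(m2$per_class$precision))
  # zero-denominator metrics are 0 with a warning
  cm3 <- matrix(0L, 4, 4)
  cm3[1, 1] <- 5
  expect_warning(m3 <- classification_metrics(cm3), "zero denominator")
  expect_equal(m3$per_class$precision[2], 0)
  expect_error(classification_metrics(matrix(0, 0, 0)), "non-empty|empty")
})

test_that("Welch t-test matches the closed-form computation", {
  welch_oracle <- function(a, b) {
    va <- var(a) / length(a)
    vb <- var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    list(t = t, df = df, p = 2 * pt(-abs(t), df))
  }
  a <- c(0.2, 0.5, 0.9, 0.4, 0.7)
  b <- c(0.6, 0.8, 0.95, 0.75)
  got <- augmentation_effect_ttest(a, b)
  want <- welch_oracle(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df, tolerance = 1e-10)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)
  # antisymmetry
  swapped <- augmentation_effect_ttest(b, a)
  expect_equal(swapped$t, -got$t, tolerance = 1e-12)
  # identical constant samples -> p = 1
  expect_equal(augmentation_effect_ttest(c(1, 1, 1), c(1, 1, 1))$p_value, 1)
  # clearly separated samples with a tiny perturbation -> p < 0.01
  eps <- c(-1e-6, 1e-6, -1e-6, 1e-6)
  sep <- augmentation_effect_ttest(c(0, 0, 0, 0) + eps, c(1, 1, 1, 1) + eps)
  expect_lt(sep$p_value, 0.01)
})

test_that("cross_validate plumbs folds, votes and confusion consistently", {
  co <- tiny_cohort(n = 2, duration = 3, seed = 42) # 8 subjects, T = 300
  cfg <- convnet_config(dropout_rate = 0, batch_size = 64)
  tr <- train_config(max_epochs = 2, patience = 2, seed = 1)
  rep1 <- cross_validate(co, cfg, k = 2, seed = 5, train = tr)
  expect_s3_class(rep1, "evaluation_report")
  cm <- rep1$metrics$confusion
  expect_equal(sum(cm), length(co$walks)) # one vote per walk
  expect_equal(rep1$metrics$accuracy, sum(diag(cm)) / sum(cm))
  expect_true(rep1$metrics$accuracy >= 0 && rep1$metrics$accuracy <= 1)
  expect_equal(nrow(rep1$walk_results), length(co$walks))
  # reproducibility: identical rerun, identical manifest hash
  rep2 <- cross_validate(co, cfg, k = 2, seed = 5, train = tr)
  expect_identical(rep1$metadata$fold_manifest_hash,
                   rep2$metadata$fold_manifest_hash)
  expect_identical(rep1$walk_results, rep2$walk_results)
})

test_that("compare_augmentations shares fold manifests across recipes", {
  co <- tiny_cohort(n = 2, duration = 3, seed = 43)
  cfg <- convnet_config(dropout_rate = 0, batch_size = 64)
  tr <- train_config(max_epochs = 1, patience = 1, seed = 1)
  cmp <- compare_augmentations(
    co, list(none = NULL, jitter = aug_config(operators = "jitter")),
    model_spec = cfg, k = 2, seed = 3, train = tr)
  hashes <- vapply(cmp$reports, function(r)
    r$metadata$fold_manifest_hash, "")
  expect_equal(length(unique(hashes)), 1)
  expect_setequal(unique(cmp$table$recipe), c("none", "jitter"))
  expect_equal(nrow(cmp$table), 8) # 4 classes x 2 recipes
  # single "none" recipe reproduces a plain cross_validate run
  solo <- compare_augmentations(co, list(none = NULL), model_spec = cfg,
                                k = 2, seed = 3, train = tr)
  direct <- cross_validate(co, cfg, k = 2, seed = 3, train = tr)
  expect_equal(solo$reports$none$metrics$confusion,
               direct$metrics$confusion)
})

test_that("sensor ablation drops exactly one pair and validates names", {
  co <- tiny_cohort(n = 2, duration = 3, seed = 44)
  cfg <- convnet_config(dropout_rate = 0, batch_size = 64)
  tr <- train_config(max_epochs = 1, patience = 1, seed = 1)
  ab <- sensor_ablation(co, model_spec = cfg,
                        pairs = list(c("L1", "R1"), c("TotalL", "TotalR")),
                        k = 2, seed = 2, train = tr)
  expect_equal(nrow(ab$table), 2)
  expect_true(all(ab$table$accuracy >= 0 & ab$table$accuracy <= 1))
  expect_error(
    sensor_ablation(co, model_spec = cfg, pairs = list(c("L9", "R9")),
                    k = 2, seed = 2, train = tr),
    "unknown channel")
})
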