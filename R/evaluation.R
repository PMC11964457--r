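#' Classification metrics from a confusion matrix
#'
#' One-vs-rest counts per class with precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, `F1 = 2PR/(P+R)` and overall accuracy (trace / total),
#' plus support-weighted averages. Rows of the matrix are true classes,
#' columns predicted. A zero-denominator metric is defined as 0 with a
#' warning.
#'
#' @param cm Square matrix of non-negative integer counts.
#' @return List with `per_class` data.frame (support, TP, FP, FN, TN,
#'   precision, recall, f1), `weighted` (precision, recall, f1),
#'   `accuracy` and `confusion`.
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (length(cm) == 0 || nrow(cm) != ncol(cm))
    stop("confusion matrix must be non-empty and square")
  if (any(cm < 0)) stop("confusion matrix must be non-negative")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  K <- nrow(cm)
  safe_div <- function(num, den, what, cls) {
    if (den == 0) {
      warning("zero denominator for ", what, " of class ", cls,
              "; reporting 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  per <- data.frame(class = rownames(cm) %||% as.character(seq_len(K) - 1))
  per$support <- rowSums(cm)
  per$TP <- diag(cm)
  per$FP <- colSums(cm) - diag(cm)
  per$FN <- rowSums(cm) - diag(cm)
  per$TN <- total - per$TP - per$FP - per$FN
  per$precision <- mapply(function(tp, fp, k)
    safe_div(tp, tp + fp, "precision", k), per$TP, per$FP, per$class)
  per$recall <- mapply(function(tp, fn, k)
    safe_div(tp, tp + fn, "recall", k), per$TP, per$FN, per$class)
  per$f1 <- mapply(function(p, r, k)
    safe_div(2 * p * r, p + r, "F1", k), per$precision, per$recall,
    per$class)
  w <- per$support / total
  list(per_class = per,
       weighted = c(precision = sum(w * per$precision),
                    recall = sum(w * per$recall),
                    f1 = sum(w * per$f1)),
       accuracy = sum(diag(cm)) / total,
       confusion = cm)
}

new_confusion <- function(K = 4) {
  m <- matrix(0L, K, K)
  rownames(m) <- colnames(m) <- severity_levels()[seq_len(K)]
  m
}

# tiny polynomial hash over a character scalar (kept below 2^31 so it
# stays inside R's integer-safe double range), for fold-manifest identity
fnv1a_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 127 + b) %% 2147483647
  sprintf("%08x", h)
}

fold_manifest_hash <- function(folds) {
  fnv1a_hash(paste(vapply(folds$folds, function(f)
    paste(sort(f$val_subjects), collapse = ","), ""), collapse = ";"))
}

build_model <- function(model_spec, n_channels, seed) {
  if (inherits(model_spec, "convnet_config"))
    build_convnet(model_spec, n_channels = n_channels, seed = seed)
  else if (inherits(model_spec, "transformer_config"))
    build_time_spatial_transformer(model_spec, n_channels = n_channels,
                                   seed = seed)
  else if (identical(model_spec, "convnet"))
    build_convnet(n_channels = n_channels, seed = seed)
  else if (identical(model_spec, "transformer"))
    build_time_spatial_transformer(n_channels = n_channels, seed = seed)
  else stop("model_spec must be a convnet_config, a transformer_config, ",
            "'convnet' or 'transformer'")
}

#' Subject-independent cross-validated evaluation
#'
#' For each fold: builds train/validation segment batches (training
#' augmentation appended, validation pristine), trains a fresh
#' classifier, predicts validation segments, aggregates each walk's
#' segment predictions by majority vote, and accumulates a pooled
#' confusion matrix of majority-voted walks. Segment-level counts are
#' reported alongside for transparency.
#'
#' @param dataset A `gait_dataset`.
#' @param model_spec A [convnet_config()], [transformer_config()],
#'   `"convnet"` or `"transformer"`.
#' @param aug Optional [aug_config()] applied to training walks.
#' @param lpr Optional [lpr_config()] applied to both sides.
#' @param k Folds (default 10).
#' @param seed Base seed (fold shuffle, weight init, training).
#' @param train A [train_config()].
#' @param folds Optional precomputed [assign_folds()] result (used by
#'   [compare_augmentations()] to share fold manifests).
#' @param window,overlap,n_copies Segmentation/augmentation plumbing, see
#'   [build_fold_data()].
#' @param channels Optional integer vector of channel indices to keep
#'   (sensor ablation); default all.
#' @param train_fraction Fraction of training walks retained per fold
#'   (stratified; see [build_fold_data()]); default 1.
#' @return An `evaluation_report`: pooled walk-level metrics, per-fold
#'   accuracies, per-walk results, segment-level confusion, and metadata
#'   (recipe, model, seed, fold-manifest hash).
#' @export
cross_validate <- function(dataset, model_spec, aug = NULL, lpr = NULL,
                           k = 10, seed = 1, train = train_config(),
                           folds = NULL, window = 100, overlap = 0.5,
                           n_copies = 1, channels = NULL,
                           train_fraction = 1) {
  known <- dataset$subjects[dataset$subjects$known_stage, , drop = FALSE]
  if (is.null(folds)) folds <- assign_folds(known, k, seed)
  assert_fold_partition(folds, known$subject_id)
  cm <- new_confusion()
  seg_cm <- new_confusion()
  walk_rows <- list()
  fold_rows <- list()
  for (fi in seq_along(folds$folds)) {
    fold <- folds$folds[[fi]]
    set.seed(seed + 100000L * fi) # subsampling + augmentation stream
    fd <- build_fold_data(dataset, fold, aug = aug, lpr = lpr,
                          window = window, overlap = overlap,
                          n_copies = n_copies,
                          train_fraction = train_fraction)
    if (!is.null(channels)) {
      fd$train$segments <- fd$train$segments[, , channels, drop = FALSE]
      fd$val$segments <- fd$val$segments[, , channels, drop = FALSE]
    }
    n_ch <- dim(fd$train$segments)[3]
    model <- build_model(model_spec, n_channels = n_ch, seed = seed + fi)
    tcfg <- train
    tcfg$seed <- seed + 1000L * fi
    model <- train_classifier(model, fd$train, fd$val, tcfg)
    pred <- predict_segments(model, fd$val)
    seg_cm <- seg_cm + table(
      factor(fd$val$labels, levels = 0:3),
      factor(pred$class, levels = 0:3))
    key <- paste(fd$val$provenance$subject_id, fd$val$provenance$walk_id)
    for (kk in unique(key)) {
      sel <- key == kk
      voted <- majority_vote(pred$class[sel])
      truth <- fd$val$labels[sel][1]
      cm[truth + 1L, voted + 1L] <- cm[truth + 1L, voted + 1L] + 1L
      walk_rows[[length(walk_rows) + 1L]] <- data.frame(
        fold = fi,
        subject_id = fd$val$provenance$subject_id[sel][1],
        walk_id = fd$val$provenance$walk_id[sel][1],
        label = truth, predicted = voted,
        correct = as.integer(voted == truth),
        stringsAsFactors = FALSE)
    }
    fr <- do.call(rbind, walk_rows)
    fold_rows[[fi]] <- data.frame(
      fold = fi, n_walks = sum(fr$fold == fi),
      accuracy = mean(fr$correct[fr$fold == fi]),
      best_epoch = model$best_epoch)
  }
  walk_results <- do.call(rbind, walk_rows)
  structure(list(
    metrics = classification_metrics(cm),
    segment_confusion = seg_cm,
    per_fold = do.call(rbind, fold_rows),
    walk_results = walk_results,
    metadata = list(
      model = if (is.character(model_spec)) model_spec else
        class(model_spec)[1],
      recipe = if (is.null(aug)) "none" else
        paste(aug$operators, collapse = "+"),
      lpr = if (is.null(lpr)) "none" else lpr_tag(lpr$decimation_rate),
      k = length(folds$folds), seed = seed,
      fold_manifest = lapply(folds$folds, `[[`, "val_subjects"),
      fold_manifest_hash = fold_manifest_hash(folds))
  ), class = "evaluation_report")
}

assert_fold_partition <- function(folds, subject_ids) {
  val_all <- unlist(lapply(folds$folds, `[[`, "val_subjects"))
  if (anyDuplicated(val_all) ||
      !setequal(val_all, subject_ids))
    stop("validation folds do not partition the subject set")
  for (f in folds$folds)
    if (length(intersect(f$train_subjects, f$val_subjects)))
      stop("train/validation subject overlap within a fold")
  invisible(TRUE)
}

#' @export
print.evaluation_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<evaluation_report> %s / recipe %s / lpr %s (k = %d)\n",
              x$metadata$model, x$metadata$recipe, x$metadata$lpr,
              x$metadata$k))
  cat(sprintf("  walk-level accuracy %.3f  (weighted P %.3f  R %.3f  F1 %.3f)\n",
              m$accuracy, m$weighted["precision"], m$weighted["recall"],
              m$weighted["f1"]))
  invisible(x)
}

#' Compare augmentation recipes under shared folds
#'
#' Runs [cross_validate()] once per recipe with identical fold manifests
#' and base seed (a fair-comparison guarantee, asserted on the returned
#' reports), and assembles a classes-by-metrics-by-recipes grid.
#'
#' @param dataset A `gait_dataset`.
#' @param recipes Named list of [aug_config()]s (`NULL` entries mean no
#'   augmentation).
#' @param model_spec,lpr,k,seed,train,window,overlap,n_copies Passed to
#'   [cross_validate()].
#' @return List with `reports` (one per recipe) and `table` (long-format
#'   data.frame: recipe, class, precision, recall, f1, accuracy).
#' @export
compare_augmentations <- function(dataset, recipes, model_spec = "convnet",
                                  lpr = NULL, k = 10, seed = 1,
                                  train = train_config(), window = 100,
                                  overlap = 0.5, n_copies = 1,
                                  train_fraction = 1) {
  if (!length(recipes)) stop("need at least one recipe")
  if (is.null(names(recipes)))
    names(recipes) <- paste0("recipe", seq_along(recipes))
  known <- dataset$subjects[dataset$subjects$known_stage, , drop = FALSE]
  folds <- assign_folds(known, k, seed)
  reports <- lapply(recipes, function(r)
    cross_validate(dataset, model_spec, aug = r, lpr = lpr, k = k,
                   seed = seed, train = train, folds = folds,
                   window = window, overlap = overlap,
                   n_copies = n_copies, train_fraction = train_fraction))
  hashes <- vapply(reports, function(r) r$metadata$fold_manifest_hash, "")
  stopifnot(length(unique(hashes)) == 1) # shared folds across recipes
  tab <- do.call(rbind, lapply(names(reports), function(nm) {
    pc <- reports[[nm]]$metrics$per_class
    data.frame(recipe = nm, class = pc$class, precision = pc$precision,
               recall = pc$recall, f1 = pc$f1,
               accuracy = reports[[nm]]$metrics$accuracy,
               stringsAsFactors = FALSE)
  }))
  list(reports = reports, table = tab)
}

#' Welch t-test for an augmentation effect
#'
#' Two-sample unequal-variance (Welch) t-test on per-unit results (by
#' default per-walk correctness indicators pooled over folds) without
#' versus with augmentation. Identical constant samples return p = 1.
#'
#' @param results_no_da,results_da Numeric vectors (n >= 2 each), or
#'   `evaluation_report`s (their per-walk correctness is used).
#' @return List with `t`, `df`, `p_value`, and the two sample means.
#' @export
augmentation_effect_ttest <- function(results_no_da, results_da) {
  as_vec <- function(r)
    if (inherits(r, "evaluation_report")) r$walk_results$correct else
      as.numeric(r)
  a <- as_vec(results_no_da)
  b <- as_vec(results_da)
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 observations per sample")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = NA_real_, p_value = 1,
                  mean_no_da = mean(a), mean_da = mean(b)))
    stop("zero variance in both samples with unequal means: ",
         "t statistic undefined")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_no_da = mean(a), mean_da = mean(b))
}

SENSOR_PAIRS <- list(
  c("L1", "R1"), c("L2", "R2"), c("L3", "R3"), c("L4", "R4"),
  c("L5", "R5"), c("L6", "R6"), c("L7", "R7"), c("L8", "R8"),
  c("TotalL", "TotalR"))

#' Symmetric sensor-pair ablation
#'
#' Drops each left/right sensor pair in turn (18 -> 16 input channels),
#' reruns the cross-validated evaluation, and ranks pair importance by
#' ascending accuracy: the pair whose removal hurts most (minimum
#' accuracy) is the most important.
#'
#' @param dataset A `gait_dataset`.
#' @param model_spec,aug,lpr,k,seed,train,window,overlap Passed to
#'   [cross_validate()].
#' @param pairs List of 2-element channel-name vectors; default all nine
#'   symmetric pairs (8 sensors + totals).
#' @return List with `table` (pair, accuracy, rank; rank 1 = most
#'   important) and `reports`.
#' @export
sensor_ablation <- function(dataset, model_spec = "convnet", aug = NULL,
                            lpr = NULL, pairs = SENSOR_PAIRS, k = 10,
                            seed = 1, train = train_config(),
                            window = 100, overlap = 0.5) {
  for (p in pairs)
    if (!all(p %in% VGRF_CHANNELS))
      stop("unknown channel name(s): ",
           paste(setdiff(p, VGRF_CHANNELS), collapse = ", "))
  reports <- list()
  acc <- numeric(length(pairs))
  for (i in seq_along(pairs)) {
    keep <- which(!VGRF_CHANNELS %in% pairs[[i]])
    rep_i <- cross_validate(dataset, model_spec, aug = aug, lpr = lpr,
                            k = k, seed = seed, train = train,
                            window = window, overlap = overlap,
                            channels = keep)
    acc[i] <- rep_i$metrics$accuracy
    reports[[i]] <- rep_i
  }
  nm <- vapply(pairs, paste, "", collapse = "&")
  names(reports) <- nm
  tab <- data.frame(pair = nm, accuracy = acc)
  tab$rank <- rank(tab$accuracy, ties.method = "min") # 1 = most important
  list(table = tab[order(tab$accuracy), ], reports = reports)
}
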