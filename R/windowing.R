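#' Segment one walk into fixed windows
#'
#' Splits a walk into `window`-step segments with fractional `overlap`
#' (default 100 steps, 50% overlap): starts at 0, stride, 2*stride, ...
#' while the window fits, stride = `window * (1 - overlap)`. A record
#' shorter than one window yields zero segments.
#'
#' @param record A `walk_record` (or bare T×C matrix).
#' @param window Window length in samples.
#' @param overlap Fractional overlap in \[0, 1).
#' @return List of `window`×C matrices, with a `starts` attribute giving
#'   the 0-based start indices.
#' @export
segment_walk <- function(record, window = 100, overlap = 0.5) {
  stopifnot(window >= 1, overlap >= 0, overlap < 1)
  X <- if (inherits(record, "walk_record")) record$forces else
    as.matrix(record)
  T <- nrow(X)
  stride <- max(1L, as.integer(round(window * (1 - overlap))))
  if (T < window) {
    out <- list()
    attr(out, "starts") <- integer(0)
    return(out)
  }
  starts <- seq.int(0L, T - window, by = stride)
  out <- lapply(starts, function(s) X[(s + 1):(s + window), , drop = FALSE])
  attr(out, "starts") <- starts
  out
}

#' Segment a dataset into a labelled batch
#'
#' Segments every walk and stacks the windows into an N×window×C array
#' with per-segment class labels and provenance (subject, walk, start
#' index). Walks shorter than one window are skipped with a message;
#' walks whose subject has no known severity are skipped as well.
#'
#' @param walks List of `walk_record`s.
#' @param window,overlap Passed to [segment_walk()].
#' @return An object of class `segment_batch`: list with `segments`
#'   (N×window×C array), `labels` (integer class indices 0..3) and
#'   `provenance` (data.frame subject_id, walk_id, start).
#' @export
segment_batch <- function(walks, window = 100, overlap = 0.5) {
  segs <- list()
  labels <- integer()
  prov <- list()
  n_short <- 0L
  for (w in walks) {
    if (is.na(w$severity)) next
    sl <- segment_walk(w, window, overlap)
    if (!length(sl)) {
      n_short <- n_short + 1L
      next
    }
    starts <- attr(sl, "starts")
    segs <- c(segs, sl)
    labels <- c(labels, rep(label_map_severity(w$severity), length(sl)))
    prov[[length(prov) + 1L]] <- data.frame(
      subject_id = w$subject_id, walk_id = w$walk_id, start = starts,
      stringsAsFactors = FALSE)
  }
  if (n_short > 0)
    message(n_short, " walk(s) shorter than one window excluded ",
            "from segmentation")
  n <- length(segs)
  C <- if (n) ncol(segs[[1]]) else 18L
  arr <- array(0, dim = c(n, window, C))
  for (i in seq_len(n)) arr[i, , ] <- segs[[i]]
  structure(list(segments = arr, labels = labels,
                 provenance = if (length(prov)) do.call(rbind, prov) else
                   data.frame(subject_id = character(),
                              walk_id = character(), start = integer())),
            class = "segment_batch")
}

label_map_severity <- function(severity) {
  match(severity, severity_levels()) - 1L
}

#' @export
print.segment_batch <- function(x, ...) {
  d <- dim(x$segments)
  cat(sprintf("<segment_batch> %d segments of %d steps x %d channels\n",
              d[1], d[2], d[3]))
  if (d[1]) {
    tab <- table(factor(x$labels, levels = 0:3,
                        labels = severity_levels()))
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Subject-independent fold assignment
#'
#' Shuffles the control and PD subject lists separately (seeded) and
#' splits each into `k` near-equal chunks; fold i's validation set is
#' chunk i of each group, so every fold holds about 1/k of the controls
#' and 1/k of the PD subjects, validation sets partition the subject set,
#' and all records of a subject stay on one side of the split.
#'
#' @param subjects Subjects data.frame (needs `subject_id`, `group`).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the shuffle.
#' @return An object of class `fold_assignment`: list of `k` folds, each
#'   with `train_subjects` and `val_subjects`.
#' @export
assign_folds <- function(subjects, k = 10, seed = 1) {
  if (k < 2) stop("k must be at least 2")
  for (g in c("control", "PD")) {
    n_g <- sum(subjects$group == g)
    if (n_g < k)
      stop("group '", g, "' has only ", n_g, " subjects; need >= k = ", k)
  }
  set.seed(seed)
  chunks <- function(ids) {
    ids <- sample(ids)
    split(ids, cut(seq_along(ids), k, labels = FALSE))
  }
  ctrl <- chunks(subjects$subject_id[subjects$group == "control"])
  pd <- chunks(subjects$subject_id[subjects$group == "PD"])
  all_ids <- subjects$subject_id
  folds <- lapply(seq_len(k), function(i) {
    val <- c(ctrl[[i]], pd[[i]])
    list(val_subjects = val, train_subjects = setdiff(all_ids, val))
  })
  structure(list(folds = folds, k = k, seed = seed),
            class = "fold_assignment")
}

#' Majority vote over segment predictions
#'
#' Returns the most frequent class; ties are broken by the lowest class
#' index (deterministic, favouring under-calling severity).
#'
#' @param predictions Non-empty vector of class indices.
#' @return Single class index.
#' @export
majority_vote <- function(predictions) {
  if (!length(predictions)) stop("empty prediction list")
  counts <- table(predictions)
  classes <- as.numeric(names(counts))
  winners <- classes[counts == max(counts)]
  min(winners)
}

#' Build train/validation segment batches for one fold
#'
#' Training walks are optionally augmented — augmented copies are
#' *appended* to the originals, never substituted — then segmented;
#' validation walks are segmented pristine. Any LPR transform is applied
#' to both sides identically, before augmentation-free validation
#' segmentation. Subject independence is asserted.
#'
#' @param dataset A `gait_dataset`.
#' @param fold One element of `assign_folds(...)$folds`.
#' @param aug An [aug_config()] or `NULL` for no augmentation.
#' @param lpr An [lpr_config()] or `NULL` to use raw forces.
#' @param window,overlap Segmentation parameters.
#' @param n_copies Augmented copies appended per training walk.
#' @param train_fraction Fraction of training walks retained (stratified
#'   by severity class, at least one walk per class; drawn from the
#'   ambient RNG stream). Used to study augmentation in a small-training
#'   regime; validation walks are never subsampled.
#' @return List with `train` and `val` `segment_batch`es.
#' @export
build_fold_data <- function(dataset, fold, aug = NULL, lpr = NULL,
                            window = 100, overlap = 0.5, n_copies = 1,
                            train_fraction = 1) {
  stopifnot(length(intersect(fold$train_subjects, fold$val_subjects)) == 0,
            train_fraction > 0, train_fraction <= 1)
  ids <- vapply(dataset$walks, `[[`, "", "subject_id")
  train_walks <- dataset$walks[ids %in% fold$train_subjects]
  val_walks <- dataset$walks[ids %in% fold$val_subjects]
  if (train_fraction < 1) {
    sev <- vapply(train_walks, `[[`, "", "severity")
    keep <- unlist(lapply(unique(sev), function(cl) {
      i <- which(sev == cl)
      sample(i, max(1L, round(train_fraction * length(i))))
    }))
    train_walks <- train_walks[sort(keep)]
  }
  if (!is.null(lpr)) {
    train_walks <- lapply(train_walks, lpr_transform, config = lpr)
    val_walks <- lapply(val_walks, lpr_transform, config = lpr)
  }
  if (!is.null(aug) && length(aug$operators)) {
    # seed once for the whole fold so each walk gets an independent draw
    if (!is.null(aug$seed)) set.seed(aug$seed)
    aug_stream <- aug
    aug_stream$seed <- NULL
    augmented <- list()
    for (w in train_walks)
      for (i in seq_len(n_copies))
        augmented[[length(augmented) + 1L]] <- aug_compose(w, aug_stream)
    train_walks <- c(train_walks, augmented)
  }
  list(train = segment_batch(train_walks, window, overlap),
       val = segment_batch(val_walks, window, overlap))
}
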