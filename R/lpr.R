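#' Linear-prediction-residual configuration
#'
#' Settings for the residual transform applied per channel: centered
#' moving-average smoothing, min–max normalization, keep-every-k-th
#' decimation at rate 1, 2 or 4 (effective sampling rates 100, 50 and
#' 25 Hz, tagged `lp_100`, `lp_50`, `lp_25`), then a least-squares linear
#' predictor of order `order_p` whose residual replaces the signal.
#'
#' @param smoothing_window Mean-filter window in samples (odd recommended;
#'   1 = no smoothing). Default 3.
#' @param decimation_rate One of 1, 2, 4.
#' @param order_p Number of past samples in the linear predictor.
#' @param normalize Whether to min–max normalize to \[0, 1\] after
#'   smoothing.
#' @return An object of class `lpr_config`.
#' @export
lpr_config <- function(smoothing_window = 3, decimation_rate = 1,
                       order_p = 10, normalize = TRUE) {
  if (!decimation_rate %in% c(1, 2, 4))
    stop("decimation_rate must be 1, 2 or 4")
  stopifnot(smoothing_window >= 1, order_p >= 1)
  structure(list(smoothing_window = as.integer(smoothing_window),
                 decimation_rate = as.integer(decimation_rate),
                 order_p = as.integer(order_p),
                 normalize = isTRUE(normalize)),
            class = "lpr_config")
}

lpr_tag <- function(rate) switch(as.character(rate),
                                 "1" = "lp_100", "2" = "lp_50",
                                 "4" = "lp_25")

#' Smooth and normalize one series
#'
#' Centered moving average of window `w` (edges use the shrunken window),
#' then min–max normalization to \[0, 1\]. A constant series maps to all
#' zeros.
#'
#' @param x Numeric vector.
#' @param config An [lpr_config()].
#' @return Numeric vector, same length.
#' @export
smooth_and_normalize <- function(x, config = lpr_config()) {
  if (length(x) == 0) stop("empty series")
  if (length(x) < config$smoothing_window)
    stop("series shorter than smoothing window")
  w <- config$smoothing_window
  if (w > 1) {
    sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
    # edge samples: average over the available part of the window
    half <- (w - 1L) %/% 2L
    n <- length(x)
    for (i in which(is.na(sm)))
      sm[i] <- mean(x[max(1, i - half):min(n, i + half)])
    x <- sm
  }
  if (config$normalize) {
    rng <- range(x)
    if (rng[2] == rng[1]) return(rep(0, length(x)))
    x <- (x - rng[1]) / (rng[2] - rng[1])
  }
  x
}

#' Decimate a series
#'
#' Keeps every `rate`-th sample starting at the first; output length is
#' `ceiling(length(x) / rate)`.
#'
#' @param x Numeric vector.
#' @param rate One of 1, 2, 4.
#' @return Numeric vector.
#' @export
decimate_series <- function(x, rate) {
  if (!rate %in% c(1, 2, 4)) stop("rate must be 1, 2 or 4")
  x[seq(1, length(x), by = rate)]
}

#' Estimate linear-prediction coefficients
#'
#' Least-squares fit of the order-`p` linear predictor
#' `x(n) ~ sum_k a_k x(n - k)`, minimising the squared residual over
#' `n = p+1 .. T`. Solved via QR on the lagged design matrix; a
#' rank-deficient design (e.g. an all-zero signal) falls back to a
#' ridge-regularized solve with a warning.
#'
#' @param x Numeric vector, length > 2p.
#' @param p Predictor order.
#' @return Numeric vector of coefficients `a_1..a_p`.
#' @export
estimate_lp_coeffs <- function(x, p) {
  n <- length(x)
  stopifnot(p >= 1)
  if (n <= 2 * p)
    stop("series length ", n, " too short for order ", p,
         " (need > 2p samples)")
  D <- lagged_design(x, p)
  y <- x[(p + 1):n]
  qrD <- qr(D)
  if (qrD$rank < p) {
    warning("rank-deficient linear-prediction design; ",
            "using ridge-regularized solve", call. = FALSE)
    a <- solve(crossprod(D) + diag(1e-8, p), crossprod(D, y))
    return(as.numeric(a))
  }
  as.numeric(qr.coef(qrD, y))
}

# Design matrix with column k = x lagged by k, rows n = p+1 .. T.
lagged_design <- function(x, p) {
  n <- length(x)
  D <- matrix(0, n - p, p)
  for (k in seq_len(p)) D[, k] <- x[(p + 1 - k):(n - k)]
  D
}

#' Linear prediction from past samples
#'
#' `xhat(n) = sum_k a_k x(n - k)` for `n > p`; the first `p` warmup
#' samples are returned as zeros so the output aligns with `x`.
#'
#' @param x Numeric vector.
#' @param a Coefficient vector `a_1..a_p`.
#' @return Numeric vector, same length as `x`.
#' @export
lp_predict <- function(x, a) {
  p <- length(a)
  n <- length(x)
  if (n <= p) stop("series not longer than predictor order")
  pred <- rep(0, n)
  pred[(p + 1):n] <- lagged_design(x, p) %*% a
  pred
}

#' Linear-prediction residual
#'
#' `e(n) = x(n) - sum_k a_k x(n - k)` for `n > p`; the `p` warmup samples
#' are emitted as zeros (rather than dropped) to preserve alignment for
#' windowing. The reconstruction identity `x = lp_predict(x, a) + e`
#' holds exactly beyond warmup.
#'
#' @inheritParams lp_predict
#' @return Residual vector, same length as `x`.
#' @export
lp_residual <- function(x, a) {
  p <- length(a)
  e <- x - lp_predict(x, a)
  e[seq_len(p)] <- 0
  e
}

#' Linear-prediction-residual transform of a walk record
#'
#' Applies, per channel: smoothing, min–max normalization, decimation,
#' per-channel least-squares coefficient estimation, and residual
#' computation. The result is a walk-record-shaped residual matrix at the
#' decimated sampling rate, tagged `lp_25`/`lp_50`/`lp_100` for decimation
#' rates 4/2/1.
#'
#' @param record A `walk_record`.
#' @param config An [lpr_config()].
#' @return A `walk_record` whose `forces` hold residuals (totals columns
#'   are transformed like any other channel, so the totals-sum invariant
#'   intentionally no longer applies).
#' @export
lpr_transform <- function(record, config = lpr_config()) {
  stopifnot(inherits(record, "walk_record"), inherits(config, "lpr_config"))
  X <- record$forces
  rate <- config$decimation_rate
  out_len <- ceiling(nrow(X) / rate)
  if (out_len <= 2 * config$order_p)
    stop("decimated length ", out_len, " too short for order ",
         config$order_p)
  R <- matrix(0, out_len, ncol(X))
  for (c in seq_len(ncol(X))) {
    x <- smooth_and_normalize(X[, c], config)
    x <- decimate_series(x, rate)
    if (all(x == x[1])) next # constant channel: residual stays zero
    a <- estimate_lp_coeffs(x, config$order_p)
    R[, c] <- lp_residual(x, a)
  }
  out <- record
  out$forces <- R
  colnames(out$forces) <- VGRF_CHANNELS
  out$sampling_rate <- record$sampling_rate / rate
  out$time <- record$time[seq(1, nrow(X), by = rate)]
  out$tags <- c(record$tags, lpr_tag(rate))
  out
}
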