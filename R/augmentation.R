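#' Augmentation configuration
#'
#' Selects and parameterises the seven composable time-series augmentation
#' operators. Defaults follow the standard settings for wearable-sensor
#' augmentation: jitter sigma 2 N, scaling sigma 0.1, time-warp sigma 0.2
#' with 4 knots, magnitude-warp sigma 0.2 with 4 knots, 4 permutation
#' blocks of at least 100 samples, and 1000 resampling points.
#'
#' @param operators Character vector, ordered subset of
#'   `c("jitter", "scale", "rotate", "magnitude_warp", "permute",
#'   "time_warp", "random_sample")`. Empty = identity.
#' @param sigma_jitter SD of additive Gaussian noise, newtons.
#' @param sigma_scale SD of the per-channel multiplicative factor
#'   (mean 1).
#' @param sigma_magwarp SD of magnitude-warp control points (mean 1).
#' @param sigma_timewarp SD of time-warp rate control points (mean 1).
#' @param knot Interior control points for the warping splines; a spline
#'   uses `knot + 2` control points in total.
#' @param n_perm Number of contiguous blocks for permutation.
#' @param min_seg_length Minimum block length (samples) for permutation.
#' @param n_sample Number of random time indices for random resampling.
#' @param seed Optional seed applied by [aug_compose()].
#' @return An object of class `aug_config`.
#' @export
aug_config <- function(operators = character(),
                       sigma_jitter = 2,
                       sigma_scale = 0.1,
                       sigma_magwarp = 0.2,
                       sigma_timewarp = 0.2,
                       knot = 4,
                       n_perm = 4,
                       min_seg_length = 100,
                       n_sample = 1000,
                       seed = NULL) {
  known <- c("jitter", "scale", "rotate", "magnitude_warp", "permute",
             "time_warp", "random_sample")
  bad <- setdiff(operators, known)
  if (length(bad))
    stop("unknown operator(s): ", paste(bad, collapse = ", "))
  stopifnot(sigma_jitter >= 0, sigma_scale >= 0, sigma_magwarp >= 0,
            sigma_timewarp >= 0, knot >= 1, n_perm >= 1,
            min_seg_length >= 1, n_sample >= 2)
  structure(as.list(environment())[known_fields_aug()],
            class = "aug_config")
}

known_fields_aug <- function() {
  c("operators", "sigma_jitter", "sigma_scale", "sigma_magwarp",
    "sigma_timewarp", "knot", "n_perm", "min_seg_length", "n_sample",
    "seed")
}

as_force_matrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X
}

#' Jittering: additive Gaussian noise
#'
#' Adds i.i.d. zero-mean Gaussian noise to every element. Draws from the
#' ambient RNG stream.
#'
#' @param X T×C numeric matrix (time by channel). Not mutated.
#' @param sigma Noise SD (newtons); 0 returns `X` unchanged.
#' @return T×C matrix.
#' @export
aug_jitter <- function(X, sigma = 2) {
  X <- as_force_matrix(X)
  stopifnot(sigma >= 0)
  if (sigma == 0) return(X)
  X + stats::rnorm(length(X), 0, sigma)
}

#' Scaling: one random multiplicative factor per channel
#'
#' Each channel is multiplied by a factor drawn from N(1, sigma^2).
#'
#' @inheritParams aug_jitter
#' @param sigma SD of the scaling factor; 0 returns `X` unchanged.
#' @return T×C matrix.
#' @export
aug_scale <- function(X, sigma = 0.1) {
  X <- as_force_matrix(X)
  stopifnot(sigma >= 0)
  if (sigma == 0) return(X)
  factors <- stats::rnorm(ncol(X), 1, sigma)
  sweep(X, 2, factors, `*`)
}

#' Rotation of channel triples about their mean axis
#'
#' Channels are partitioned into consecutive triples (feature groups).
#' For each triple the time-averaged 3-vector, normalised to unit length,
#' serves as a rotation axis; a rotation by a uniform random angle in
#' (-pi, pi] about that axis (Rodrigues' formula) is applied to every
#' time sample. Per-sample Euclidean norms within a triple are preserved.
#' Channels beyond the last full triple are passed through unchanged. A
#' zero-mean triple (undefined axis) falls back to the unit x-axis with a
#' warning.
#'
#' @inheritParams aug_jitter
#' @param angle Optional fixed angle in radians (one per triple, recycled);
#'   `NULL` (default) draws random angles. `angle = 0` is the identity.
#' @return T×C matrix.
#' @export
aug_rotate <- function(X, angle = NULL) {
  X <- as_force_matrix(X)
  n_groups <- ncol(X) %/% 3L
  if (n_groups == 0L) return(X)
  if (is.null(angle)) {
    theta <- stats::runif(n_groups, -pi, pi)
  } else {
    theta <- rep_len(angle, n_groups)
  }
  for (g in seq_len(n_groups)) {
    cols <- (3L * (g - 1L) + 1L):(3L * g)
    axis <- colMeans(X[, cols, drop = FALSE])
    nrm <- sqrt(sum(axis^2))
    if (nrm == 0) {
      warning("rotation group ", g,
              " has zero mean; using fixed unit axis", call. = FALSE)
      axis <- c(1, 0, 0)
    } else {
      axis <- axis / nrm
    }
    R <- rodrigues_matrix(axis, theta[g])
    X[, cols] <- X[, cols, drop = FALSE] %*% t(R)
  }
  X
}

# Rotation matrix about unit axis k by angle theta (Rodrigues' formula).
rodrigues_matrix <- function(k, theta) {
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Smooth random curve through `knot + 2` control values ~ N(1, sigma^2)
# at equally spaced positions over 1..T, cubic-spline interpolated.
random_curve <- function(T, sigma, knot) {
  ctrl_x <- seq(1, T, length.out = knot + 2L)
  ctrl_y <- stats::rnorm(knot + 2L, 1, sigma)
  stats::splinefun(ctrl_x, ctrl_y, method = "natural")(seq_len(T))
}

#' Magnitude warping: smooth random amplitude envelope
#'
#' Multiplies each channel elementwise by a smooth random curve obtained
#' by cubic-spline interpolation through `knot + 2` control values drawn
#' from N(1, sigma^2) at equally spaced positions.
#'
#' @inheritParams aug_jitter
#' @param sigma SD of the control values; 0 gives an exact identity.
#' @param knot Number of interior control points.
#' @return T×C matrix.
#' @export
aug_magnitude_warp <- function(X, sigma = 0.2, knot = 4) {
  X <- as_force_matrix(X)
  stopifnot(sigma >= 0, knot >= 1, nrow(X) >= 2)
  if (sigma == 0) return(X)
  for (c in seq_len(ncol(X)))
    X[, c] <- X[, c] * random_curve(nrow(X), sigma, knot)
  X
}

#' Permutation: shuffle contiguous time blocks
#'
#' Splits the series at random cut points into `n_perm` contiguous blocks,
#' each at least `min_seg_length` samples long, and concatenates the
#' blocks in random order. All channels share one block order, so rows are
#' rearranged but never altered.
#'
#' @inheritParams aug_jitter
#' @param n_perm Number of blocks; 1 is the identity.
#' @param min_seg_length Minimum block length in samples. Because the
#'   default equals the downstream window length, permutation must be
#'   applied to full-length walks, before windowing.
#' @return T×C matrix.
#' @export
aug_permute <- function(X, n_perm = 4, min_seg_length = 100) {
  X <- as_force_matrix(X)
  T <- nrow(X)
  stopifnot(n_perm >= 1, min_seg_length >= 1)
  if (T < n_perm * min_seg_length)
    stop("series of length ", T, " too short for ", n_perm,
         " blocks of at least ", min_seg_length, " samples")
  if (n_perm == 1) return(X)
  # lengths = min_seg_length each + random split of the slack
  slack <- T - n_perm * min_seg_length
  cuts <- sort(sample.int(slack + 1L, n_perm - 1L, replace = TRUE) - 1L)
  extra <- diff(c(0L, cuts, slack))
  lens <- min_seg_length + extra
  ends <- cumsum(lens)
  starts <- c(1L, ends[-n_perm] + 1L)
  order <- sample.int(n_perm)
  idx <- unlist(lapply(order, function(b) starts[b]:ends[b]))
  X[idx, , drop = FALSE]
}

#' Time warping: smooth random distortion of the time axis
#'
#' For each channel, a smooth positive "rate" curve is generated (cubic
#' spline through `knot + 2` control values ~ N(1, sigma^2), clipped below
#' at 1e-3 to guarantee monotonicity); its cumulative sum, rescaled to
#' span \[1, T\], defines a strictly increasing warped time axis at which
#' the channel is linearly re-interpolated.
#'
#' @inheritParams aug_jitter
#' @param sigma SD of the rate control values; 0 is the identity up to
#'   interpolation error below 1e-9.
#' @param knot Number of interior control points.
#' @return T×C matrix (length preserved).
#' @export
aug_time_warp <- function(X, sigma = 0.2, knot = 4) {
  X <- as_force_matrix(X)
  stopifnot(sigma >= 0, knot >= 1)
  T <- nrow(X)
  for (c in seq_len(ncol(X))) {
    tw <- warped_time_axis(T, sigma, knot)
    X[, c] <- stats::approx(seq_len(T), X[, c], xout = tw)$y
  }
  X
}

# Strictly increasing warped time axis over [1, T].
warped_time_axis <- function(T, sigma, knot) {
  rate <- pmax(random_curve(T, sigma, knot), 1e-3)
  cum <- cumsum(rate)
  1 + (cum - cum[1]) / (cum[T] - cum[1]) * (T - 1)
}

#' Random sampling: sparse resampling with linear interpolation
#'
#' For each channel, `n_sample` random time indices are drawn (sorted,
#' with the first and last forced to the series endpoints); the channel's
#' values at those indices are linearly re-interpolated back onto the full
#' grid. Endpoints are always preserved, and a linear ramp is reproduced
#' exactly for any `n_sample >= 2`.
#'
#' @inheritParams aug_jitter
#' @param n_sample Number of retained indices (>= 2). Values >= T keep all
#'   samples.
#' @return T×C matrix.
#' @export
aug_random_sample <- function(X, n_sample = 1000) {
  X <- as_force_matrix(X)
  T <- nrow(X)
  stopifnot(n_sample >= 2)
  for (c in seq_len(ncol(X))) {
    if (n_sample >= T) {
      idx <- seq_len(T)
    } else {
      idx <- sort(c(1L, sample(2:(T - 1L), n_sample - 2L), T))
    }
    X[, c] <- stats::approx(idx, X[idx, c], xout = seq_len(T))$y
  }
  X
}

#' Compose augmentation operators
#'
#' Applies the operators listed in `config$operators`, in order, to a
#' force matrix or to the `forces` of a `walk_record`. An empty operator
#' list is the identity. If `config$seed` is set the ambient RNG is seeded
#' first, making the composition reproducible. A `walk_record` input is
#' returned as a new record tagged with the recipe.
#'
#' @param x T×C matrix or `walk_record`.
#' @param config An [aug_config()].
#' @return Same type as `x`.
#' @export
aug_compose <- function(x, config) {
  stopifnot(inherits(config, "aug_config"))
  if (inherits(x, "walk_record")) {
    out <- x
    out$forces <- aug_compose(x$forces, config)
    colnames(out$forces) <- VGRF_CHANNELS
    out$tags <- c(x$tags,
                  paste0("aug:", paste(config$operators, collapse = "+")))
    return(out)
  }
  X <- as_force_matrix(x)
  if (!is.null(config$seed)) set.seed(config$seed)
  for (op in config$operators) {
    X <- switch(op,
      jitter = aug_jitter(X, config$sigma_jitter),
      scale = aug_scale(X, config$sigma_scale),
      rotate = aug_rotate(X),
      magnitude_warp = aug_magnitude_warp(X, config$sigma_magwarp,
                                          config$knot),
      permute = aug_permute(X, config$n_perm, config$min_seg_length),
      time_warp = aug_time_warp(X, config$sigma_timewarp, config$knot),
      random_sample = aug_random_sample(X, config$n_sample))
  }
  X
}
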