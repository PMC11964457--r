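test_that("all seven operators are the identity at zero-strength settings", {
  X <- tiny_forces(T = 400)
  set.seed(1)
  expect_identical(aug_jitter(X, 0), X)
  expect_identical(aug_scale(X, 0), X)
  expect_equal(aug_rotate(X, angle = 0), X, tolerance = 1e-9)
  expect_identical(aug_magnitude_warp(X, 0, 4), X)
  expect_identical(aug_permute(X, 1, 100), X)
  expect_equal(aug_time_warp(X, 0), X, tolerance = 1e-9)
  expect_equal(aug_random_sample(X, nrow(X)), X)
})

test_that("operators preserve shape and never mutate their input", {
  X <- tiny_forces(T = 450)
  X_copy <- X + 0
  set.seed(2)
  for (f in list(function(x) aug_jitter(x, 2),
                 function(x) aug_scale(x, 0.1),
                 function(x) aug_rotate(x),
                 function(x) aug_magnitude_warp(x, 0.2, 4),
                 function(x) aug_permute(x, 4, 100),
                 function(x) aug_time_warp(x, 0.2, 4),
                 function(x) aug_random_sample(x, 200))) {
    Y <- f(X)
    expect_identical(dim(Y), dim(X))
    expect_identical(X, X_copy)
  }
})

test_that("jitter adds zero-mean noise with the configured sigma", {
  set.seed(3)
  X <- matrix(0, 10000, 1)
  Y <- aug_jitter(X, 2)
  expect_gt(sd(Y), 1.94)
  expect_lt(sd(Y), 2.06)
  expect_lt(abs(mean(Y)), 0.07)
})

test_that("scaling multiplies each channel by one constant factor", {
  X <- tiny_forces(T = 200) + 1 # strictly positive
  set.seed(4)
  Y <- aug_scale(X, 0.1)
  ratio <- Y / X
  for (c in seq_len(ncol(X)))
    expect_lt(diff(range(ratio[, c])), 1e-12)
  # factor distribution: sd ~ 0.1 over many draws
  set.seed(5)
  factors <- replicate(2000, aug_scale(matrix(1, 2, 1), 0.1)[1, 1])
  expect_lt(abs(sd(factors) - 0.1), 0.01)
  expect_lt(abs(mean(factors) - 1), 0.01)
})

test_that("rotation preserves per-sample norms within channel triples", {
  X <- tiny_forces(T = 300)
  set.seed(6)
  Y <- aug_rotate(X)
  for (g in seq_len(6)) {
    cols <- (3 * (g - 1) + 1):(3 * g)
    expect_equal(sqrt(rowSums(Y[, cols]^2)), sqrt(rowSums(X[, cols]^2)),
                 tolerance = 1e-9)
  }
  # zero-mean group falls back with a warning
  Z <- cbind(matrix(c(1, -1), 10, 3), tiny_forces(10)[, 4:18])
  Z[, 1:3] <- rep(c(1, -1), 5)
  set.seed(7)
  expect_warning(aug_rotate(Z), "zero mean")
})

test_that("magnitude warping applies the same smooth curve it generated", {
  X <- matrix(1, 500, 3) # unit input exposes the curve directly
  set.seed(8)
  Y <- aug_magnitude_warp(X, 0.2, 4)
  # reconstruct the curves from the same seeded stream
  set.seed(8)
  for (c in 1:3) {
    curve <- gaitsev:::random_curve(500, 0.2, 4)
    expect_equal(Y[, c], curve, tolerance = 1e-12)
  }
  # knot = 4 means exactly 6 control points: the curve generator consumes
  # precisely knot + 2 draws from the RNG stream
  set.seed(9)
  invisible(gaitsev:::random_curve(500, 0.2, 4))
  after_curve <- rnorm(1)
  set.seed(9)
  invisible(rnorm(6))
  expect_identical(after_curve, rnorm(1))
})

test_that("permutation rearranges whole rows in valid blocks", {
  X <- tiny_forces(T = 500)
  set.seed(10)
  Y <- aug_permute(X, 4, 100)
  expect_same_multiset(X, Y)
  expect_error(aug_permute(X[1:300, ], 4, 100), "too short")
  # block lengths always >= min_seg_length: recover maximal runs of
  # consecutive original indices from a marker column (adjacent blocks
  # that land next to each other merge into longer runs, so every
  # detected run must still be >= 100 and there are at most 4)
  M <- cbind(seq_len(500), matrix(0, 500, 17))
  set.seed(11)
  for (i in 1:20) {
    P <- aug_permute(M, 4, 100)
    breaks <- which(diff(P[, 1]) != 1)
    lens <- diff(c(0, breaks, 500))
    expect_true(all(lens >= 100))
    expect_lte(length(lens), 4)
  }
})

test_that("time warping keeps a strictly increasing time axis", {
  set.seed(12)
  for (i in 1:25) {
    tw <- gaitsev:::warped_time_axis(400, 0.3, 4)
    expect_true(all(diff(tw) > 0))
    expect_equal(tw[1], 1)
    expect_equal(tw[400], 400)
  }
  X <- tiny_forces(T = 400)
  set.seed(13)
  expect_identical(dim(aug_time_warp(X, 0.2, 4)), dim(X))
})

test_that("random sampling preserves endpoints and linear ramps exactly", {
  T <- 400
  ramp <- matrix(seq(-3, 7, length.out = T), T, 5)
  set.seed(14)
  for (ns in c(2, 10, 100)) {
    Y <- aug_random_sample(ramp, ns)
    expect_equal(Y, ramp, tolerance = 1e-9)
  }
  X <- tiny_forces(T)
  set.seed(15)
  Y <- aug_random_sample(X, 50)
  expect_equal(Y[1, ], X[1, ])
  expect_equal(Y[T, ], X[T, ])
})

test_that("composition applies operators in order, reproducibly", {
  X <- tiny_forces(T = 500)
  cfg0 <- aug_config()
  expect_identical(aug_compose(X, cfg0), X)
  cfg_zero <- aug_config(operators = c("jitter", "scale"),
                         sigma_jitter = 0, sigma_scale = 0, seed = 1)
  expect_identical(aug_compose(X, cfg_zero), X)
  cfg <- aug_config(operators = c("jitter", "permute"), seed = 123)
  Y1 <- aug_compose(X, cfg)
  Y2 <- aug_compose(X, cfg)
  expect_identical(Y1, Y2)
  # a walk_record comes back tagged
  w <- tiny_walk(T = 500)
  wa <- aug_compose(w, cfg)
  expect_true(any(grepl("aug:jitter\\+permute", wa$tags)))
  expect_identical(dim(wa$forces), dim(w$forces))
})

test_that("label-preserving operators barely move class-mean statistics", {
  # jitter and scale leave the stance-duration statistic essentially
  # unchanged on a synthetic walk
  set.seed(16)
  w <- simulate_walk(gait_sim_config(duration = 15, seed = 16), 2)
  s0 <- stance_fraction_stat(w)
  set.seed(17)
  wj <- aug_compose(w, aug_config(operators = "jitter"))
  ws <- aug_compose(w, aug_config(operators = "scale"))
  expect_lt(abs(stance_fraction_stat(wj) - s0), 0.05)
  expect_lt(abs(stance_fraction_stat(ws) - s0), 0.05)
})

test_that("unknown operators and invalid parameters are rejected", {
  expect_error(aug_config(operators = "flip"), "unknown operator")
  expect_error(aug_config(sigma_jitter = -1))
  expect_error(aug_config(n_sample = 1))
})
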