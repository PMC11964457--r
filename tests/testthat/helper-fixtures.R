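# Shared fixtures, all generated in code.

# Small deterministic force matrix with exact totals.
tiny_forces <- function(T = 300, seed = 42) {
  set.seed(seed)
  f <- matrix(abs(stats::rnorm(T * 16, 50, 20)), T, 16)
  cbind(f, rowSums(f[, 1:8]), rowSums(f[, 9:16]))
}

tiny_walk <- function(T = 300, seed = 42, ...) {
  walk_record(time = seq(0, by = 0.01, length.out = T),
              forces = tiny_forces(T, seed), subject_id = "S1", ...)
}

# Small synthetic cohort shared by several tests.
tiny_cohort <- function(n = 2, duration = 10, seed = 7, ...) {
  simulate_cohort(gait_sim_config(n_subjects_per_class = n,
                                  duration = duration, seed = seed, ...))
}

# Tiny ConvNet for fast model tests.
tiny_convnet_config <- function(...) {
  convnet_config(dropout_rate = 0, batch_size = 32, ...)
}

expect_same_multiset <- function(A, B) {
  expect_equal(dim(A), dim(B))
  oA <- do.call(order, as.data.frame(A))
  oB <- do.call(order, as.data.frame(B))
  expect_equal(unname(A[oA, , drop = FALSE]), unname(B[oB, , drop = FALSE]))
}
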