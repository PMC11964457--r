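test_that("totals are exact sums of their sensors, with and without noise", {
  cfg <- gait_sim_config(duration = 10, seed = 1)
  set.seed(1)
  w <- simulate_walk(cfg, 2)
  expect_equal(unname(w$forces[, 17]), rowSums(w$forces[, 1:8]))
  expect_equal(unname(w$forces[, 18]), rowSums(w$forces[, 9:16]))
  cfg0 <- gait_sim_config(duration = 10, sensor_noise_sd = 0, seed = 1)
  set.seed(1)
  w0 <- simulate_walk(cfg0, 0)
  expect_identical(unname(w0$forces[, 17]), rowSums(w0$forces[, 1:8]))
  expect_true(all(w$forces >= 0))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- gait_sim_config(duration = 8, seed = 5)
  set.seed(99); w1 <- simulate_walk(cfg, 3)
  set.seed(99); w2 <- simulate_walk(cfg, 3)
  expect_identical(w1$forces, w2$forces)
  co1 <- simulate_cohort(gait_sim_config(n_subjects_per_class = 1,
                                         duration = 5, seed = 3))
  co2 <- simulate_cohort(gait_sim_config(n_subjects_per_class = 1,
                                         duration = 5, seed = 3))
  expect_identical(co1$walks[[4]]$forces, co2$walks[[4]]$forces)
})

test_that("walk shape matches config and short durations error", {
  cfg <- gait_sim_config(duration = 12, seed = 2)
  set.seed(2)
  w <- simulate_walk(cfg, 1)
  expect_equal(n_samples(w), 1200)
  expect_error(simulate_walk(gait_sim_config(duration = 1.5), 0),
               "2 stride periods")
})

test_that("higher severity yields longer high-pressure (stance) durations", {
  cfg <- gait_sim_config(duration = 20, sensor_noise_sd = 0, seed = 4)
  set.seed(4)
  stats <- vapply(0:3, function(cls)
    stance_fraction_stat(simulate_walk(cfg, cls,
                                       subject_params = list(
                                         amp_mult = 1, stance_shift = 0))),
    0)
  expect_true(all(diff(stats) > 0))
  # class 3 spends more time above half-peak than class 0 as well
  set.seed(4)
  f0 <- stance_fraction_stat(simulate_walk(cfg, 0), threshold = 0.5)
  set.seed(4)
  f3 <- stance_fraction_stat(simulate_walk(cfg, 3), threshold = 0.5)
  expect_gt(f3, f0)
})

test_that("cohort counts follow the config", {
  co <- simulate_cohort(gait_sim_config(n_subjects_per_class = 10,
                                        n_walks_per_subject = 2,
                                        duration = 4, seed = 6))
  expect_equal(length(co$walks), 80)
  expect_equal(nrow(co$subjects), 40)
  expect_equal(unname(table(co$subjects$severity)[severity_levels()]),
               rep(10L, 4), ignore_attr = TRUE)
  # group/stage coupling
  expect_true(all((co$subjects$group == "control") ==
                    (co$subjects$hoehn_yahr == "healthy")))
})

test_that("per-class mean stance fraction recovers configured values", {
  cfg <- gait_sim_config(n_subjects_per_class = 20, duration = 20, seed = 8)
  co <- simulate_cohort(cfg)
  cls <- vapply(co$walks, function(w)
    label_map(co$subjects$hoehn_yahr[
      co$subjects$subject_id == w$subject_id]), 0L)
  est <- vapply(co$walks, stance_fraction_stat, 0)
  for (k in 0:3) {
    m <- mean(est[cls == k])
    expect_lt(abs(m - cfg$stance_fraction[k + 1]) /
                cfg$stance_fraction[k + 1], 0.05)
  }
})

test_that("subject random effects induce within-subject correlation", {
  co <- simulate_cohort(gait_sim_config(n_subjects_per_class = 6,
                                        n_walks_per_subject = 2,
                                        duration = 10, seed = 9))
  ids <- vapply(co$walks, `[[`, "", "subject_id")
  amp <- vapply(co$walks, function(w) mean(w$forces[, "TotalL"]), 0)
  # between-walk gap within subject vs between subjects of the same class
  sev <- vapply(co$walks, `[[`, "", "severity")
  within <- mean(vapply(unique(ids), function(s)
    abs(diff(amp[ids == s])), 0))
  subj_mean <- tapply(amp, ids, mean)
  subj_cls <- tapply(sev, ids, `[`, 1)
  across <- mean(unlist(lapply(unique(subj_cls), function(cl) {
    a <- subj_mean[subj_cls == cl]
    d <- abs(outer(a, a, "-"))
    d[upper.tri(d)]
  })))
  expect_lt(within, across)
})

test_that("planted-signal mode confines class effects to chosen sensors", {
  base <- gait_sim_config(duration = 15, sensor_noise_sd = 0,
                          informative_sensors = 2, seed = 10)
  sp <- list(amp_mult = 1, stance_shift = 0)
  set.seed(10); w0 <- simulate_walk(base, 0, subject_params = sp)
  set.seed(10); w3 <- simulate_walk(base, 3, subject_params = sp)
  # uninformative sensor channels are identical across classes
  for (ch in c("L1", "L5", "R8"))
    expect_equal(w0$forces[, ch], w3$forces[, ch])
  # the planted pair differs strongly
  expect_gt(mean(abs(w0$forces[, "L2"] - w3$forces[, "L2"])), 1)
  expect_gt(mean(abs(w0$forces[, "R2"] - w3$forces[, "R2"])), 1)
})

test_that("degenerate class-parameter configs are rejected", {
  expect_error(gait_sim_config(stance_fraction = c(0.6, 0.6, 0.7, 0.8)),
               "increasing")
  expect_error(gait_sim_config(cycle_jitter_sd = c(0.02, 0.01, 0.03, 0.04)),
               "non-decreasing")
})
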