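#' Configuration for the synthetic gait simulator
#'
#' The simulator emulates the statistical structure of plantar VGRF
#' recordings that severity classifiers exploit: 100 Hz sampling,
#' roughly two-minute walks, quasi-periodic alternating-foot stance bursts
#' with a double-peak ("M") force profile on each of 8 sensors per foot,
#' total-force channels that are exact sums of their sensors, and three
#' severity-graded effects — longer relative stance (high-pressure)
#' durations, growing left/right amplitude asymmetry, and growing
#' cycle-to-cycle timing variability.
#'
#' @param n_subjects_per_class Subjects simulated per severity class.
#' @param n_walks_per_subject Walks recorded per subject.
#' @param duration Walk duration in seconds (default 120, a two-minute
#'   walk).
#' @param cadence Stride rate per foot in strides/s (default 1.0).
#' @param stance_fraction Length-4 vector, fraction of the stride period a
#'   foot spends loaded, per class; must be strictly increasing with
#'   severity.
#' @param asymmetry Length-4 vector, right/left amplitude ratio per class;
#'   1 = symmetric gait.
#' @param cycle_jitter_sd Length-4 vector, SD in seconds of stance-onset
#'   timing noise per class; must be non-decreasing with severity.
#' @param amplitude_profile Length-8 vector of per-sensor peak forces in
#'   newtons (same layout for both feet before asymmetry).
#' @param sensor_noise_sd SD in newtons of i.i.d. sensor noise added to the
#'   16 sensor channels (forces are clipped at 0; totals are computed after
#'   noise so they remain exact sums).
#' @param subject_amp_sd SD of the per-subject log-amplitude random effect.
#' @param subject_stance_sd SD of the per-subject stance-fraction random
#'   effect (drawn once per subject, so walks of a subject are correlated).
#' @param informative_sensors Integer vector of sensor indices (1–8) that
#'   carry the class signal, or `NULL` (default) for all. When set, the
#'   remaining sensors and the stride schedule use class-0 (healthy)
#'   parameters — a planted-signal mode used to validate sensor ablation.
#' @param seed Integer seed used by [simulate_cohort()].
#' @return An object of class `gait_sim_config`.
#' @export
gait_sim_config <- function(n_subjects_per_class = 10,
                            n_walks_per_subject = 1,
                            duration = 120,
                            cadence = 1.0,
                            stance_fraction = c(0.55, 0.64, 0.73, 0.82),
                            asymmetry = c(1.00, 0.92, 0.84, 0.76),
                            cycle_jitter_sd = c(0.005, 0.015, 0.025, 0.035),
                            amplitude_profile = c(90, 30, 110, 70,
                                                  100, 60, 120, 140),
                            sensor_noise_sd = 3,
                            subject_amp_sd = 0.08,
                            subject_stance_sd = 0.012,
                            informative_sensors = NULL,
                            seed = 1L) {
  stopifnot(n_subjects_per_class >= 1, n_walks_per_subject >= 1,
            duration > 0, cadence > 0,
            length(stance_fraction) == 4, length(asymmetry) == 4,
            length(cycle_jitter_sd) == 4, length(amplitude_profile) == 8,
            sensor_noise_sd >= 0)
  if (any(diff(stance_fraction) <= 0))
    stop("stance_fraction must be strictly increasing with severity class")
  if (any(diff(cycle_jitter_sd) < 0))
    stop("cycle_jitter_sd must be non-decreasing with severity class")
  if (any(stance_fraction <= 0 | stance_fraction >= 1))
    stop("stance_fraction must lie in (0, 1)")
  if (!is.null(informative_sensors) &&
      !all(informative_sensors %in% 1:8))
    stop("informative_sensors must be sensor indices in 1..8")
  structure(as.list(environment()), class = "gait_sim_config")
}

# Double-peak stance profile on u in [0,1]: two overlapping raised-cosine
# lobes (heel-strike and toe-off peaks) with a mid-stance dip.
stance_profile <- function(u) {
  lobe <- function(u, centre, width) {
    v <- (u - centre) / width
    ifelse(abs(v) < 1, 0.5 * (1 + cos(pi * v)), 0)
  }
  lobe(u, 0.25, 0.35) + lobe(u, 0.75, 0.35)
}

# Per-subject random effects, drawn once per subject from the ambient RNG.
draw_subject_params <- function(config) {
  list(amp_mult = exp(stats::rnorm(1, 0, config$subject_amp_sd)),
       stance_shift = stats::rnorm(1, 0, config$subject_stance_sd))
}

#' Simulate one walk
#'
#' Generates a `walk_record` for one subject and severity class. Uses the
#' ambient RNG stream; seed via `set.seed()` (or use [simulate_cohort()],
#' which seeds from its config) — two calls with the same seed, config and
#' arguments produce identical records.
#'
#' @param config A [gait_sim_config()].
#' @param class_index Severity class in 0..3 (0 = healthy).
#' @param subject_id,walk_id Identifiers stored on the record.
#' @param subject_params Optional per-subject random effects from an
#'   enclosing cohort simulation; drawn fresh if `NULL`.
#' @return A `walk_record` with exact total-force columns.
#' @export
simulate_walk <- function(config, class_index, subject_id = "S1",
                          walk_id = "w1", subject_params = NULL) {
  stopifnot(inherits(config, "gait_sim_config"),
            class_index %in% 0:3)
  period <- 1 / config$cadence
  if (config$duration < 2 * period)
    stop("duration must cover at least 2 stride periods")
  if (is.null(subject_params))
    subject_params <- draw_subject_params(config)
  ci <- class_index + 1L
  fs <- 100
  tt <- seq(0, config$duration - 1 / fs, by = 1 / fs)
  T <- length(tt)

  planted <- !is.null(config$informative_sensors)
  info <- if (planted) config$informative_sensors else 1:8
  # schedule-level severity knobs use class 0 in planted mode
  jitter_sd <- config$cycle_jitter_sd[if (planted) 1L else ci]
  # per-sensor stance fraction and amplitude side-ratio
  f_base <- config$stance_fraction[1L] + subject_params$stance_shift
  f_class <- config$stance_fraction[ci] + subject_params$stance_shift
  sensor_frac <- rep(f_base, 8)
  sensor_frac[info] <- f_class
  sensor_frac <- pmin(pmax(sensor_frac, 0.2), 0.95)
  asym <- rep(1, 8)
  asym[info] <- config$asymmetry[ci]

  forces <- matrix(0, T, 18)
  n_strides <- ceiling(config$duration / period) + 1L
  for (foot in 1:2) { # 1 = left, 2 = right
    offset <- if (foot == 1) 0 else period / 2
    onsets <- offset + (seq_len(n_strides) - 1L) * period +
      stats::rnorm(n_strides, 0, jitter_sd)
    side_amp <- config$amplitude_profile * subject_params$amp_mult *
      (if (foot == 2) asym else 1)
    stance_amp <- stats::rnorm(n_strides, 1, 0.05)
    cols <- if (foot == 1) 1:8 else 9:16
    for (k in seq_len(n_strides)) {
      for (f_val in unique(sensor_frac)) {
        dur <- f_val * period
        i0 <- max(1L, ceiling(onsets[k] * fs) + 1L)
        i1 <- min(T, floor((onsets[k] + dur) * fs) + 1L)
        if (i0 > i1) next
        prof <- stance_profile((tt[i0:i1] - onsets[k]) / dur) * stance_amp[k]
        sel <- which(sensor_frac == f_val)
        forces[i0:i1, cols[sel]] <- forces[i0:i1, cols[sel], drop = FALSE] +
          outer(prof, side_amp[sel])
      }
    }
  }
  if (config$sensor_noise_sd > 0)
    forces[, 1:16] <- forces[, 1:16] +
      stats::rnorm(T * 16L, 0, config$sensor_noise_sd)
  forces[forces < 0] <- 0
  forces[, 17] <- rowSums(forces[, 1:8, drop = FALSE])
  forces[, 18] <- rowSums(forces[, 9:16, drop = FALSE])

  walk_record(time = tt, forces = forces, subject_id = subject_id,
              walk_id = walk_id, study = "Syn",
              group = if (class_index == 0) "control" else "PD",
              severity = severity_levels()[ci], total_tol = 1e-9)
}

#' Simulate a labelled cohort
#'
#' Simulates `n_subjects_per_class` subjects in each of the four severity
#' classes, each with `n_walks_per_subject` walks. Subject-level random
#' effects are drawn once per subject, so a subject's walks are correlated
#' — the structure the subject-independent cross-validation tests rely on.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [gait_sim_config()].
#' @return A `gait_dataset`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "gait_sim_config"))
  set.seed(config$seed)
  walks <- list()
  rows <- list()
  stages <- c("healthy", "2", "2.5", "3")
  for (cls in 0:3) {
    for (s in seq_len(config$n_subjects_per_class)) {
      sid <- sprintf("C%dS%02d", cls, s)
      sp <- draw_subject_params(config)
      for (w in seq_len(config$n_walks_per_subject)) {
        walks[[length(walks) + 1L]] <-
          simulate_walk(config, cls, subject_id = sid,
                        walk_id = sprintf("w%d", w), subject_params = sp)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, study = "Syn",
        group = if (cls == 0) "control" else "PD",
        hoehn_yahr = stages[cls + 1L],
        age = round(stats::rnorm(1, 65, 8)),
        sex = sample(c("M", "F"), 1),
        height = round(stats::rnorm(1, 1.70, 0.08), 2),
        weight = round(stats::rnorm(1, 72, 10), 1),
        stringsAsFactors = FALSE)
    }
  }
  gait_dataset(walks, as_subject_table(do.call(rbind, rows)))
}

#' Mean stance fraction of a walk
#'
#' Diagnostic statistic: the fraction of samples whose left total force
#' exceeds a threshold fraction of its peak. Used to verify that simulated
#' classes are ordered by their configured stance fractions.
#'
#' @param record A `walk_record`.
#' @param threshold Fraction of the channel peak counting as "loaded".
#' @param channel Channel name (default `"TotalL"`).
#' @return Numeric scalar in \[0, 1\].
#' @export
stance_fraction_stat <- function(record, threshold = 0.2,
                                 channel = "TotalL") {
  x <- record$forces[, channel]
  mean(x > threshold * max(x))
}
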