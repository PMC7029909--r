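#' Simulation configuration for a synthetic sheep flock
#'
#' Bundles every knob of the ear-tag IMU simulator: sampling rate, recording
#' length, activity bout durations, flock composition and the magnitude of the
#' lameness-dependent signal perturbations. Defaults mirror the field study
#' this package models: 16 Hz sampling and a flock of 10 non-lame plus 13 lame
#' sheep-day recordings.
#'
#' @param sampling_rate Sampling frequency in Hz. Default 16.
#' @param recording_duration Length of one sheep-day recording in seconds.
#' @param bout_duration_range Named list with elements `walking`, `standing`,
#'   `lying`, each a length-2 numeric vector giving the uniform bout-duration
#'   range in seconds.
#' @param n_lame,n_nonlame Number of lame (locomotion score >= 2) and non-lame
#'   (score 0-1) sheep-day recordings in the flock.
#' @param noise_sd_accel Accelerometer sensor noise SD in g.
#' @param noise_sd_gyro Gyroscope sensor noise SD in degrees/s.
#' @param lame_frequency_shift Gait-frequency shift in Hz per unit effect size
#'   for lame walking.
#' @param headnod_amplitude Head-nod accelerometer amplitude in g per unit
#'   effect size (lame walking only; phase-jittered, at half the stride
#'   frequency).
#' @param burst_rate_standing Baseline weight-shift burst rate while standing,
#'   events per minute. Lame sheep shift weight more often: the rate is
#'   multiplied by `1 + 2 * effect_size`.
#' @param restlessness_rate_lying Baseline restlessness event rate while
#'   lying, events per minute; same lameness scaling as standing bursts.
#' @param rng_seed Integer seed; the whole flock is a deterministic function
#'   of config + profiles + seed.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(recording_duration = 300, rng_seed = 1)
#' cfg$sampling_rate
#' @export
sim_config <- function(sampling_rate = 16,
                       recording_duration = 1800,
                       bout_duration_range = list(walking  = c(6, 20),
                                                  standing = c(15, 45),
                                                  lying    = c(30, 90)),
                       n_lame = 13,
                       n_nonlame = 10,
                       noise_sd_accel = 0.02,
                       noise_sd_gyro = 2,
                       lame_frequency_shift = 0.25,
                       headnod_amplitude = 0.05,
                       burst_rate_standing = 8,
                       restlessness_rate_lying = 6,
                       rng_seed = 1L) {
  if (sampling_rate <= 0) stop_ovi("`sampling_rate` must be positive (got %s)", sampling_rate)
  if (recording_duration <= 0) {
    stop_ovi("`recording_duration` must be positive (got %s seconds)", recording_duration)
  }
  if (!all(ACTIVITIES %in% names(bout_duration_range))) {
    stop_ovi("`bout_duration_range` needs entries for %s", paste(ACTIVITIES, collapse = ", "))
  }
  for (a in ACTIVITIES) {
    r <- bout_duration_range[[a]]
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
      stop_ovi("bout_duration_range$%s must be an increasing positive pair", a)
    }
  }
  rates <- c(burst_rate_standing, restlessness_rate_lying,
             lame_frequency_shift, headnod_amplitude)
  if (any(rates < 0)) stop_ovi("rates and perturbation amplitudes must be >= 0")
  if (n_lame < 0 || n_nonlame < 0) stop_ovi("flock counts must be >= 0")
  structure(list(
    sampling_rate = sampling_rate,
    recording_duration = recording_duration,
    bout_duration_range = bout_duration_range,
    n_lame = as.integer(n_lame),
    n_nonlame = as.integer(n_nonlame),
    noise_sd_accel = noise_sd_accel,
    noise_sd_gyro = noise_sd_gyro,
    lame_frequency_shift = lame_frequency_shift,
    headnod_amplitude = headnod_amplitude,
    burst_rate_standing = burst_rate_standing,
    restlessness_rate_lying = restlessness_rate_lying,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

#' Build a flock of sheep profiles
#'
#' One profile per sheep-day recording. Non-lame sheep draw a locomotion score
#' from \{0, 1\}, lame sheep from \{2, 3\} (the observed field range); the
#' binary class is lame <=> score >= 2. All sheep share the same default gait
#' frequency: because windows from the same sheep land in both training and
#' test folds under lameness-only stratification, any label-independent
#' per-sheep signature would let a classifier shortcut through sheep identity;
#' a common baseline keeps the null (effect_size = 0) truly uninformative.
#'
#' @param config A [sim_config()].
#' @param effect_size Non-negative scalar scaling every lameness perturbation;
#'   0 makes lame and non-lame generators identical.
#' @param gait_frequency Stride frequency in Hz used by every sheep.
#' @param activity_budget Named proportions over walking/standing/lying,
#'   summing to 1. Defaults mirror the field dataset's window composition.
#' @return Tibble with one row per sheep: `sheep_id`, `lameness_score`,
#'   `lame`, `budget_walking`, `budget_standing`, `budget_lying`,
#'   `gait_frequency`, `effect_size`.
#' @examples
#' sheep_profiles(sim_config(rng_seed = 7))
#' @export
sheep_profiles <- function(config,
                           effect_size = 1,
                           gait_frequency = 1.5,
                           activity_budget = c(walking = 0.32, standing = 0.37, lying = 0.31)) {
  stopifnot(inherits(config, "sim_config"))
  if (effect_size < 0) stop_ovi("`effect_size` must be >= 0")
  validate_budget(activity_budget)
  n <- config$n_lame + config$n_nonlame
  if (n < 1) stop_ovi("flock is empty: n_lame + n_nonlame must be >= 1")
  lame <- rep(c(FALSE, TRUE), c(config$n_nonlame, config$n_lame))
  set.seed(config$rng_seed)
  score <- ifelse(lame, sample(2:3, n, replace = TRUE), sample(0:1, n, replace = TRUE))
  tibble(
    sheep_id = sprintf("sheep_%02d", seq_len(n)),
    lameness_score = as.integer(score),
    lame = lame,
    budget_walking = unname(activity_budget["walking"]),
    budget_standing = unname(activity_budget["standing"]),
    budget_lying = unname(activity_budget["lying"]),
    gait_frequency = gait_frequency,
    effect_size = effect_size
  )
}

validate_budget <- function(budget) {
  if (!all(ACTIVITIES %in% names(budget))) {
    stop_ovi("activity budget needs named proportions for %s", paste(ACTIVITIES, collapse = ", "))
  }
  if (any(budget < 0)) stop_ovi("activity budget proportions must be >= 0")
  if (abs(sum(budget) - 1) > 1e-9) {
    stop_ovi("activity budget must sum to 1 (got %.12f)", sum(budget))
  }
  invisible(budget)
}

validate_profile <- function(profile) {
  needed <- c("sheep_id", "lameness_score", "budget_walking", "budget_standing",
              "budget_lying", "gait_frequency", "effect_size")
  missing <- setdiff(needed, names(profile))
  if (length(missing)) stop_ovi("profile is missing fields: %s", paste(missing, collapse = ", "))
  if (!profile$lameness_score %in% 0:6) {
    stop_ovi("lameness_score must be an integer in 0..6 (got %s)", profile$lameness_score)
  }
  b <- c(walking = profile$budget_walking, standing = profile$budget_standing,
         lying = profile$budget_lying)
  validate_budget(b)
  if (profile$effect_size < 0) stop_ovi("effect_size must be >= 0")
  invisible(profile)
}
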