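#' Magnitude and magnitude-difference signals
#'
#' `compute_magnitude()` collapses the three axes of one sensor modality to
#' the pointwise Euclidean norm (the acceleration magnitude in g, or the
#' gyroscope magnitude in degrees/s). `magnitude_difference()` takes the
#' per-sample first difference of a magnitude series, `d[i] = m[i+1] - m[i]`,
#' which removes any static component (gravity, fixed ear-tag orientation)
#' exactly; the result is one sample shorter than its source.
#'
#' @param recording A `triaxial_recording`.
#' @param modality `"accel"` or `"gyro"`.
#' @return A `magnitude_series`: list with `values`, `modality`,
#'   `sampling_rate` and a `differenced` flag.
#' @examples
#' m <- magnitude_series(c(5, 5, 5, 5), "accel", 16)
#' magnitude_difference(m)$values  # c(0, 0, 0)
#' @export
compute_magnitude <- function(recording, modality = c("accel", "gyro")) {
  stopifnot(inherits(recording, "triaxial_recording"))
  modality <- match.arg(modality)
  s <- recording$sensors
  v <- if (modality == "accel") {
    sqrt(s$ax_g^2 + s$ay_g^2 + s$az_g^2)
  } else {
    sqrt(s$gx_dps^2 + s$gy_dps^2 + s$gz_dps^2)
  }
  magnitude_series(v, modality, recording$sampling_rate)
}

#' @rdname compute_magnitude
#' @param values Numeric vector of magnitudes (all >= 0).
#' @param sampling_rate Sampling rate in Hz.
#' @export
magnitude_series <- function(values, modality = c("accel", "gyro"), sampling_rate) {
  modality <- match.arg(modality)
  if (any(values < 0)) stop_ovi("magnitude values must be >= 0")
  structure(list(values = values, modality = modality,
                 sampling_rate = sampling_rate, differenced = FALSE),
            class = "magnitude_series")
}

#' @rdname compute_magnitude
#' @param series A `magnitude_series`.
#' @export
magnitude_difference <- function(series) {
  stopifnot(inherits(series, "magnitude_series"))
  if (length(series$values) < 2) {
    stop_ovi("cannot difference a series of length %d (need >= 2)", length(series$values))
  }
  structure(list(values = diff(series$values), modality = series$modality,
                 sampling_rate = series$sampling_rate, differenced = TRUE),
            class = "magnitude_series")
}

#' Segment differenced signals into overlapping annotated windows
#'
#' Cuts the two differenced magnitude streams into fixed-length windows
#' (7 s, i.e. 112 samples at 16 Hz, by default) with 50% overlap between
#' consecutive windows. Window boundaries are indexed on the differenced
#' stream, so every window holds exactly `window_s * sampling_rate`
#' differenced samples. Each window is labelled with the activity covering
#' the majority of its samples; windows whose leading activity covers less
#' than half the window, ties, and windows with no annotation coverage are
#' dropped. The lameness label is per recording (lame <=> locomotion
#' score >= 2).
#'
#' @param accel_diff,gyro_diff Differenced `magnitude_series` of equal length
#'   and sampling rate.
#' @param annotations Tibble with `sheep_id, start_s, end_s, activity,
#'   lameness_score` (non-overlapping intervals).
#' @param window_s Window length in seconds; `window_s * sampling_rate` must
#'   be an integer.
#' @param overlap Fractional overlap between consecutive windows, in [0, 1).
#' @param accel_mag,gyro_mag Optional un-differenced source
#'   `magnitude_series`, used to flag windows whose raw sensor magnitude is
#'   identically zero (see [remove_erroneous()]).
#' @return Tibble with one row per retained window: `sheep_id`,
#'   `window_index`, `start_s`, `activity`, `lame`, `lameness_score`,
#'   list-columns `accel_diff` and `gyro_diff` (each a numeric vector of
#'   length `window_s * sampling_rate`), and logical error flags
#'   `accel_src_zero`, `gyro_src_zero`.
#' @export
segment_windows <- function(accel_diff, gyro_diff, annotations,
                            window_s = 7, overlap = 0.5,
                            accel_mag = NULL, gyro_mag = NULL) {
  stopifnot(inherits(accel_diff, "magnitude_series"), inherits(gyro_diff, "magnitude_series"))
  if (length(accel_diff$values) != length(gyro_diff$values)) {
    stop_ovi("accel and gyro differenced series differ in length (%d vs %d)",
             length(accel_diff$values), length(gyro_diff$values))
  }
  fs <- accel_diff$sampling_rate
  if (fs != gyro_diff$sampling_rate) stop_ovi("sampling rates differ across modalities")
  wlen <- window_s * fs
  if (abs(wlen - round(wlen)) > 1e-9) {
    stop_ovi("window_s * sampling_rate must be an integer (got %s)", wlen)
  }
  wlen <- as.integer(round(wlen))
  if (overlap < 0 || overlap >= 1) stop_ovi("overlap must be in [0, 1)")
  step <- as.integer(round(wlen * (1 - overlap)))
  if (step < 1) stop_ovi("overlap too large: window step is below one sample")

  n <- length(accel_diff$values)
  if (n < wlen) return(empty_window_tibble())
  starts <- seq.int(1L, n - wlen + 1L, by = step)

  # per-sample annotation label on the differenced stream: differenced sample
  # i summarises raw samples i and i+1; it is stamped with the time of raw
  # sample i (0-based), t = (i - 1) / fs
  ann <- arrange(annotations, .data$start_s)
  t_samp <- (seq_len(n) - 1) / fs
  idx <- findInterval(t_samp + 1e-12, ann$start_s)
  act <- rep(NA_character_, n)
  inside <- idx >= 1 & t_samp < ann$end_s[pmax(idx, 1)] + 1e-12
  act[inside] <- ann$activity[idx[inside]]

  score <- max(ann$lameness_score)
  sheep <- ann$sheep_id[1]

  rows <- purrr::map(seq_along(starts), function(k) {
    i0 <- starts[k]
    span <- i0:(i0 + wlen - 1L)
    lab <- window_majority_label(act[span])
    if (is.na(lab)) return(NULL)
    tibble(
      sheep_id = sheep,
      window_index = k,
      start_s = (i0 - 1) / fs,
      activity = lab,
      lame = score >= 2,
      lameness_score = as.integer(score),
      accel_diff = list(accel_diff$values[span]),
      gyro_diff = list(gyro_diff$values[span]),
      accel_src_zero = source_all_zero(accel_mag, i0, wlen),
      gyro_src_zero = source_all_zero(gyro_mag, i0, wlen)
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) empty_window_tibble() else out
}

empty_window_tibble <- function() {
  tibble(sheep_id = character(), window_index = integer(), start_s = numeric(),
         activity = character(), lame = logical(), lameness_score = integer(),
         accel_diff = list(), gyro_diff = list(),
         accel_src_zero = logical(), gyro_src_zero = logical())
}

# majority activity over the window span; NA when coverage < 50% or tied
window_majority_label <- function(labels) {
  wlen <- length(labels)
  tab <- table(labels[!is.na(labels)])
  if (length(tab) == 0) return(NA_character_)
  mx <- max(tab)
  if (mx < wlen / 2) return(NA_character_)
  winners <- names(tab)[tab == mx]
  if (length(winners) > 1) return(NA_character_)
  winners
}

# differenced window [i0, i0+wlen-1] draws on raw samples i0..i0+wlen
source_all_zero <- function(mag, i0, wlen) {
  if (is.null(mag)) return(NA)
  span <- i0:min(i0 + wlen, length(mag$values))
  all(mag$values[span] == 0)
}

#' Drop windows with erroneous (all-zero) sensor data
#'
#' A window whose raw accelerometer magnitude is identically zero across the
#' whole window — i.e. the sensor reported (0, 0, 0) for every sample — is
#' treated as a recording fault and removed; the same rule applies to the
#' gyroscope. Windows with isolated zero samples are retained, and input
#' order is preserved.
#'
#' @param windows Window tibble from [segment_windows()].
#' @return The filtered window tibble.
#' @export
remove_erroneous <- function(windows) {
  stopifnot(is.data.frame(windows))
  bad <- (windows$accel_src_zero %in% TRUE) | (windows$gyro_src_zero %in% TRUE)
  windows[!bad, , drop = FALSE]
}

#' Preprocess recordings into feature-ready windows
#'
#' Convenience wrappers running the full preprocessing chain on one recording
#' (`preprocess_recording()`) or a list of recordings (`preprocess_flock()`):
#' magnitude, first difference, overlapping windows, majority activity
#' labels, and removal of all-zero (erroneous) windows.
#'
#' @param recording A `triaxial_recording`; `flock` is a list of them.
#' @inheritParams segment_windows
#' @return A window tibble (see [segment_windows()]).
#' @examples
#' cfg <- sim_config(recording_duration = 120, n_lame = 1, n_nonlame = 1, rng_seed = 5)
#' flock <- simulate_flock(cfg, sheep_profiles(cfg))
#' wins <- preprocess_flock(flock)
#' dplyr::count(wins, activity)
#' @export
preprocess_recording <- function(recording, window_s = 7, overlap = 0.5) {
  am <- compute_magnitude(recording, "accel")
  gm <- compute_magnitude(recording, "gyro")
  w <- segment_windows(magnitude_difference(am), magnitude_difference(gm),
                       recording$annotations, window_s, overlap,
                       accel_mag = am, gyro_mag = gm)
  remove_erroneous(w)
}

#' @rdname preprocess_recording
#' @param flock List of recordings, e.g. from [simulate_flock()].
#' @export
preprocess_flock <- function(flock, window_s = 7, overlap = 0.5) {
  stopifnot(is.list(flock), length(flock) > 0)
  purrr::map_dfr(flock, preprocess_recording, window_s = window_s, overlap = overlap)
}
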