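#' Time-domain window statistics
#'
#' The eight order/moment statistics computed on one window of the
#' differenced magnitude signal: mean, standard deviation (sample SD),
#' minimum, maximum, median, skewness, kurtosis and interquartile range
#' (Q3 - Q1, linear-interpolation quantiles). Skewness and kurtosis are
#' population moment estimators, kurtosis is excess kurtosis, and both are 0
#' by convention on a zero-variance window.
#'
#' @param values Numeric window (length >= 4).
#' @return Named numeric vector of length 8.
#' @examples
#' time_domain_stats(c(1, 2, 3, 4))
#' @export
time_domain_stats <- function(values) {
  if (length(values) < 4) stop_ovi("window too short for moment statistics (need >= 4)")
  s <- sd(values)
  qs <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  if (s == 0) {
    sk <- 0
    ku <- 0
  } else {
    sk <- e1071::skewness(values, type = 1)
    ku <- e1071::kurtosis(values, type = 1)
  }
  c(mean = mean(values), std = s, min = min(values), max = max(values),
    median = median(values), skewness = sk, kurtosis = ku, iqr = qs[2] - qs[1])
}

#' Zero crossings of a mean-subtracted window
#'
#' Subtracts the window mean, then counts sign changes between consecutive
#' samples. Samples that are exactly zero carry the previous nonzero sign
#' (so `1, 0, -1` is one crossing, not two).
#'
#' @param values Numeric window (length >= 2).
#' @return Integer count.
#' @examples
#' zero_crossings(c(1, -1, 1, -1))  # 3
#' @export
zero_crossings <- function(values) {
  if (length(values) < 2) stop_ovi("need at least 2 samples to count crossings")
  x <- values - mean(values)
  s <- sign(x)
  nz <- s != 0
  if (!any(nz)) return(0L)
  s <- s[nz]
  sum(s[-1] != s[-length(s)])
}

#' Signal area of a window
#'
#' `SA = sum(|Mag|) / f_s`: the rectangle-rule area under the rectified
#' signal, a proxy for overall movement intensity. The differenced magnitude
#' is near zero-mean, so the rectified form is used by default; set
#' `absolute = FALSE` for the literal signed sum.
#'
#' @param values Numeric window.
#' @param f_s Sampling frequency in Hz.
#' @param absolute Rectify before summing (default `TRUE`).
#' @return Scalar signal area (g.s or deg/s.s).
#' @examples
#' signal_area(rep(0.5, 112), 16)  # 3.5
#' @export
signal_area <- function(values, f_s, absolute = TRUE) {
  if (length(values) == 0) stop_ovi("empty window")
  if (f_s <= 0) stop_ovi("f_s must be positive")
  v <- if (absolute) abs(values) else values
  sum(v) / f_s
}

#' One-sided power spectrum of a window
#'
#' Plain (un-tapered, un-detrended) DFT periodogram. Bins run from DC to the
#' Nyquist frequency with spacing `delta_f = f_s / n`. `psd` is the
#' two-sided power spectral density `|X_k|^2 / (n^2 * delta_f)`; `power` is
#' the one-sided per-bin power (interior bins doubled) whose sum equals the
#' window mean square (Parseval); `psd_norm` normalises `power` to sum to 1.
#' An all-zero window yields a spectrum flagged `degenerate`, for which all
#' downstream spectral features take their degenerate defaults (0).
#'
#' @param values Numeric window (length >= 8).
#' @param f_s Sampling frequency in Hz.
#' @return A `power_spectrum`: list with `frequencies`, `psd`, `power`,
#'   `psd_norm`, `amplitudes`, `delta_f`, `n_bins`, `n`, `degenerate`.
#' @examples
#' sp <- compute_spectrum(cos(2 * pi * 2 * (0:111) / 16), f_s = 16)
#' sp$frequencies[which.max(sp$power)]  # 2 Hz
#' @export
compute_spectrum <- function(values, f_s) {
  n <- length(values)
  if (n < 8) stop_ovi("window too short for a spectrum (need >= 8 samples)")
  if (f_s <= 0) stop_ovi("f_s must be positive")
  nb <- floor(n / 2) + 1L           # bins 0..floor(n/2)
  delta_f <- f_s / n
  X <- fft(values)[seq_len(nb)]
  amp <- Mod(X)
  p2 <- amp^2 / n^2                 # two-sided per-bin power
  one_sided <- p2
  interior <- seq(2L, nb - if (n %% 2 == 0) 1L else 0L)
  one_sided[interior] <- 2 * one_sided[interior]
  degenerate <- all(values == 0)
  total <- sum(one_sided)
  psd_norm <- if (degenerate || total == 0) rep(0, nb) else one_sided / total
  structure(list(
    frequencies = (seq_len(nb) - 1) * delta_f,
    psd = p2 / delta_f,
    power = one_sided,
    psd_norm = psd_norm,
    amplitudes = amp,
    delta_f = delta_f,
    n_bins = nb,
    n = n,
    degenerate = degenerate
  ), class = "power_spectrum")
}

#' Spectral features of a window
#'
#' * `spectral_entropy()`: Shannon entropy `-sum(PSD_norm * log(PSD_norm))`
#'   (natural log; empty bins contribute 0); low for rhythmic movement,
#'   up to `log(n_bins)` for irregular movement.
#' * `dominant_frequencies()`: the three distinct non-DC bins of highest
#'   power, in descending power order (ties broken toward the lower
#'   frequency) — the dominant frequency and the 2nd and 3rd harmonic
#'   frequencies.
#' * `spectral_area()`: `SpA = 2 * sum_{n>=1} S(f_n) * delta_f`, the total
#'   dynamic signal power (DC excluded); approximates the window variance.
#' * `harmonic_ratio()`: ratio of summed even-indexed to summed odd-indexed
#'   DFT amplitudes (DC excluded), a gait-symmetry proxy. With
#'   `mode = "dominant"` the indexing runs over multiples of the dominant
#'   bin instead of raw bin numbers. A zero denominator yields 0.
#'
#' All four return their degenerate default (0, or `c(0, 0, 0)`) on a
#' degenerate (all-zero) spectrum.
#'
#' @param spectrum A `power_spectrum` from [compute_spectrum()].
#' @return `spectral_entropy`, `spectral_area`, `harmonic_ratio`: scalar.
#'   `dominant_frequencies`: named vector `c(dominant, second, third)` in Hz.
#' @examples
#' sp <- compute_spectrum(sin(2 * pi * 1.5 * (0:111) / 16), 16)
#' spectral_entropy(sp)
#' dominant_frequencies(sp)
#' @export
spectral_entropy <- function(spectrum) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (spectrum$degenerate) return(0)
  p <- spectrum$psd_norm
  p <- p[p > 0]
  -sum(p * log(p))
}

#' @rdname spectral_entropy
#' @export
dominant_frequencies <- function(spectrum) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  out <- c(dominant = 0, second = 0, third = 0)
  if (spectrum$degenerate || spectrum$n_bins < 4) return(out)
  pw <- spectrum$power[-1]          # DC excluded
  fr <- spectrum$frequencies[-1]
  ord <- order(-pw, fr)             # ties toward lower frequency
  take <- fr[ord[seq_len(min(3, length(ord)))]]
  out[seq_along(take)] <- take
  out
}

#' @rdname spectral_entropy
#' @export
spectral_area <- function(spectrum) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (spectrum$degenerate) return(0)
  2 * spectrum$delta_f * sum(spectrum$psd[-1])
}

#' @rdname spectral_entropy
#' @param mode Bin indexing for the even/odd amplitude sums: `"bins"`
#'   (raw DFT bin indices, default) or `"dominant"` (multiples of the
#'   dominant bin).
#' @export
harmonic_ratio <- function(spectrum, mode = c("bins", "dominant")) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  mode <- match.arg(mode)
  if (spectrum$degenerate) return(0)
  amp <- spectrum$amplitudes
  nb <- spectrum$n_bins
  if (mode == "bins") {
    idx <- seq(2L, nb)              # bins 1..N (1-based storage: DC at 1)
    k <- idx - 1L
    even <- sum(amp[idx[k %% 2 == 0]])
    odd <- sum(amp[idx[k %% 2 == 1]])
  } else {
    pw <- spectrum$power[-1]
    kd <- which.max(pw)             # dominant non-DC bin index
    harm <- kd * seq_len((nb - 1) %/% kd)
    a <- amp[harm + 1L]
    even <- sum(a[seq_along(a) %% 2 == 0])
    odd <- sum(a[seq_along(a) %% 2 == 1])
  }
  if (odd == 0) 0 else even / odd
}

#' Canonical feature names
#'
#' The 16 per-modality characteristics in their fixed order, prefixed with
#' the modality (`accel_`/`gyro_`) in the 32-column feature table.
#'
#' @param modality `NULL` for the bare 16 names, or `"accel"`/`"gyro"`/
#'   `"both"` for prefixed names.
#' @return Character vector of feature names.
#' @export
feature_names <- function(modality = "both") {
  base <- c("mean", "std", "min", "max", "median", "skewness", "kurtosis", "iqr",
            "zero_crossings", "signal_area", "spectral_entropy",
            "dominant_frequency", "spectral_area",
            "harmonic_freq2", "harmonic_freq3", "harmonic_ratio")
  if (is.null(modality)) return(base)
  switch(modality,
         accel = paste0("accel_", base),
         gyro = paste0("gyro_", base),
         both = c(paste0("accel_", base), paste0("gyro_", base)),
         stop_ovi("unknown modality '%s'", modality))
}

# all 16 characteristics for one window of one modality
window_features <- function(values, f_s, sa_absolute = TRUE, hr_mode = "bins") {
  td <- time_domain_stats(values)
  sp <- compute_spectrum(values, f_s)
  dom <- dominant_frequencies(sp)
  c(td,
    zero_crossings = as.numeric(zero_crossings(values)),
    signal_area = signal_area(values, f_s, absolute = sa_absolute),
    spectral_entropy = spectral_entropy(sp),
    dominant_frequency = unname(dom["dominant"]),
    spectral_area = spectral_area(sp),
    harmonic_freq2 = unname(dom["second"]),
    harmonic_freq3 = unname(dom["third"]),
    harmonic_ratio = harmonic_ratio(sp, mode = hr_mode))
}

#' Extract the 32-feature vector for each window
#'
#' Applies the 16 characteristics of [feature_names()] to the accelerometer
#' and gyroscope differenced-magnitude samples of every window, yielding the
#' 32-column feature table that is the contract between preprocessing and
#' modelling. Deterministic: each row depends only on its own window.
#'
#' @param windows Window tibble from [preprocess_flock()] /
#'   [segment_windows()].
#' @param f_s Sampling frequency in Hz.
#' @param sa_absolute Rectify the signal before the signal-area sum
#'   (default `TRUE`; see [signal_area()]).
#' @param hr_mode Harmonic-ratio indexing (see [harmonic_ratio()]).
#' @return Tibble: `sheep_id`, `window_index`, `activity`, `lame`, then the
#'   32 feature columns in [feature_names()] order.
#' @examples
#' cfg <- sim_config(recording_duration = 120, n_lame = 1, n_nonlame = 1, rng_seed = 5)
#' wins <- preprocess_flock(simulate_flock(cfg, sheep_profiles(cfg)))
#' feats <- extract_features(wins, f_s = 16)
#' dim(feats)
#' @export
extract_features <- function(windows, f_s = 16, sa_absolute = TRUE, hr_mode = "bins") {
  stopifnot(is.data.frame(windows))
  if (nrow(windows) == 0) {
    out <- matrix(numeric(0), 0, 32, dimnames = list(NULL, feature_names("both")))
    return(bind_cols(tibble(sheep_id = character(), window_index = integer(),
                            activity = character(), lame = logical()),
                     as_tibble(out)))
  }
  fmat <- t(vapply(seq_len(nrow(windows)), function(i) {
    c(window_features(windows$accel_diff[[i]], f_s, sa_absolute, hr_mode),
      window_features(windows$gyro_diff[[i]], f_s, sa_absolute, hr_mode))
  }, numeric(32)))
  colnames(fmat) <- feature_names("both")
  bind_cols(
    tibble(sheep_id = windows$sheep_id,
           window_index = windows$window_index,
           activity = windows$activity,
           lame = windows$lame),
    as_tibble(fmat)
  )
}
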