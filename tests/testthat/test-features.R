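cosine_window <- function(freq, n = 112, fs = 16, amp = 1, phase = 0) {
  amp * cos(2 * pi * freq * (0:(n - 1)) / fs + phase)
}

fake_spectrum <- function(power, fs = 16, n = 112) {
  # hand-built spectrum object for closed-form entropy/tie checks
  nb <- length(power)
  structure(list(frequencies = (0:(nb - 1)) * fs / n,
                 psd = power / (fs / n), power = power,
                 psd_norm = if (sum(power) > 0) power / sum(power) else power,
                 amplitudes = sqrt(power), delta_f = fs / n, n_bins = nb,
                 n = n, degenerate = all(power == 0)),
            class = "power_spectrum")
}

test_that("time-domain statistics match hand-computed values", {
  s <- time_domain_stats(c(1, 2, 3, 4))
  expect_equal(unname(s[c("mean", "min", "max", "iqr", "median")]),
               c(2.5, 1, 4, 1.5, 2.5))
  cst <- time_domain_stats(rep(3, 10))
  expect_equal(unname(cst[c("std", "skewness", "kurtosis")]), c(0, 0, 0))
  sym <- time_domain_stats(c(-2, -1, 1, 2))
  expect_equal(unname(sym["skewness"]), 0)
  expect_error(time_domain_stats(c(1, 2)), "too short")
})

test_that("zero crossings follow the carried-sign rule", {
  expect_equal(zero_crossings(c(1, -1, 1, -1)), 3)
  expect_equal(zero_crossings(rep(2, 10)), 0L)
  expect_equal(zero_crossings(c(1, 0, -1)), 1)
})

test_that("signal area is the rectified rectangle-rule sum", {
  expect_equal(signal_area(rep(0.5, 112), 16), 3.5)
  expect_equal(signal_area(rep(0, 50), 16), 0)
  expect_equal(signal_area(c(1, -1, 1, -1), 16), 0.25)
  expect_equal(signal_area(c(1, -1, 1, -1), 16, absolute = FALSE), 0)
})

test_that("the periodogram concentrates pure tones and satisfies Parseval", {
  x <- cosine_window(2)                      # bin 14 of 112 at 16 Hz
  sp <- compute_spectrum(x, 16)
  expect_equal(sp$delta_f, 1 / 7)
  expect_equal(sp$n_bins, 57)
  pk <- which.max(sp$power)
  expect_equal(sp$frequencies[pk], 2)
  expect_true(all(sp$power[-pk] <= 1e-10 * sp$power[pk]))

  set.seed(7)
  y <- rnorm(112)
  spy <- compute_spectrum(y, 16)
  expect_equal(sum(spy$power), mean(y^2), tolerance = 1e-10)
})

test_that("spectral entropy has its closed-form values", {
  expect_equal(spectral_entropy(fake_spectrum(c(0, 1, rep(0, 55)))), 0)
  expect_equal(spectral_entropy(fake_spectrum(rep(1, 57))), log(57))
  two <- rep(0, 57); two[c(5, 9)] <- 1
  expect_equal(spectral_entropy(fake_spectrum(two)), log(2))
  expect_equal(spectral_entropy(compute_spectrum(rep(0, 112), 16)), 0)
})

test_that("dominant and harmonic frequencies rank spectral peaks, DC excluded", {
  expect_equal(unname(dominant_frequencies(compute_spectrum(cosine_window(2), 16))["dominant"]), 2)
  x <- 3 * cosine_window(2) + 2 * cosine_window(1) + 1 * cosine_window(3)
  expect_equal(unname(dominant_frequencies(compute_spectrum(x, 16))), c(2, 1, 3))
  # flat spectrum: tie rule forces the three lowest non-DC bins
  expect_equal(unname(dominant_frequencies(fake_spectrum(rep(1, 57)))),
               c(1, 2, 3) * 16 / 112)
  # DC offset never wins
  expect_equal(unname(dominant_frequencies(compute_spectrum(cosine_window(2) + 100, 16))["dominant"]), 2)
  expect_equal(unname(dominant_frequencies(compute_spectrum(rep(0, 112), 16))), c(0, 0, 0))
})

test_that("spectral area recovers signal power", {
  expect_equal(spectral_area(compute_spectrum(rep(0, 112), 16)), 0)
  set.seed(3)
  spas <- replicate(200, spectral_area(compute_spectrum(rnorm(112), 16)))
  expect_lt(abs(mean(spas) - 1), 0.1)
  x <- cosine_window(2.5) + 0.3 * cosine_window(5)
  expect_equal(spectral_area(compute_spectrum(2 * x, 16)),
               4 * spectral_area(compute_spectrum(x, 16)))
})

test_that("harmonic ratio contrasts even against odd DFT bins", {
  even_tone <- cosine_window(2)              # bin 14: even
  odd_tone <- cosine_window(1.5)             # bin 10.5 -> use bin 13 = 13/7 Hz
  odd_tone <- cosine_window(13 * 16 / 112)
  expect_gt(harmonic_ratio(compute_spectrum(even_tone, 16)), 100)
  expect_lt(harmonic_ratio(compute_spectrum(odd_tone, 16)), 0.01)
  expect_equal(harmonic_ratio(compute_spectrum(rep(0, 112), 16)), 0)
})

test_that("spectral features agree with a brute-force DFT oracle", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(1) * cosine_window(runif(1, 0.5, 7), phase = runif(1, 0, 2 * pi)) +
      0.1 * rnorm(112)
    o <- oracle_spectral(x, 16)
    sp <- compute_spectrum(x, 16)
    expect_equal(spectral_entropy(sp), o$se, tolerance = 1e-8)
    expect_equal(unname(dominant_frequencies(sp)), c(o$dominant, o$second, o$third),
                 tolerance = 1e-12)
    expect_equal(spectral_area(sp), o$spa, tolerance = 1e-8)
    expect_equal(harmonic_ratio(sp), o$hr, tolerance = 1e-8)
  }
})

test_that("feature extraction yields 32 finite, deterministic, per-window values", {
  w <- preprocess_flock(small_flock(seed = 14, duration = 150))
  f <- extract_features(w)
  expect_equal(ncol(f), 36)
  expect_named(f, c("sheep_id", "window_index", "activity", "lame",
                    feature_names("both")))
  expect_true(all(is.finite(as.matrix(f[, feature_names("both")]))))

  # determinism and order independence: each row depends only on its window
  idx <- rev(seq_len(nrow(w)))
  f_rev <- extract_features(w[idx, ])
  expect_equal(as.data.frame(f_rev), as.data.frame(f[idx, ]), ignore_attr = TRUE)

  # modality independence: zeroed accel gives degenerate accel features only
  w0 <- w[1, ]
  w0$accel_diff[[1]] <- rep(0, 112)
  f0 <- extract_features(w0)
  expect_equal(unname(unlist(f0[1, feature_names("accel")])), rep(0, 16))
  expect_equal(f0[1, feature_names("gyro")], f[1, feature_names("gyro")])
})

test_that("amplitude scaling acts as expected on SE, SA and SpA", {
  set.seed(15)
  v <- rnorm(112)
  w1 <- tibble::tibble(sheep_id = "s", window_index = 1L, activity = "lying",
                       lame = FALSE, lameness_score = 0L,
                       accel_diff = list(v), gyro_diff = list(v),
                       accel_src_zero = FALSE, gyro_src_zero = FALSE)
  w3 <- w1
  w3$accel_diff[[1]] <- 3 * v
  w3$gyro_diff[[1]] <- 3 * v
  f1 <- extract_features(w1); f3 <- extract_features(w3)
  expect_equal(f3$accel_spectral_entropy, f1$accel_spectral_entropy)
  expect_equal(f3$accel_signal_area, 3 * f1$accel_signal_area)
  expect_equal(f3$accel_spectral_area, 9 * f1$accel_spectral_area)
})
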