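make_diff_series <- function(n, fs = 16, modality = "accel", seed = 1) {
  set.seed(seed)
  structure(list(values = rnorm(n), modality = modality,
                 sampling_rate = fs, differenced = TRUE),
            class = "magnitude_series")
}

full_annotation <- function(duration, activity = "walking", score = 0L) {
  tibble::tibble(sheep_id = "s1", start_s = 0, end_s = duration,
                 activity = activity, lameness_score = score)
}

test_that("magnitude is the pointwise Euclidean norm", {
  rec <- structure(list(
    sheep_id = "s", sampling_rate = 16, lameness_score = 0L,
    sensors = tibble::tibble(
      timestamp_s = (0:2) / 16,
      ax_g = c(3, 0, 1), ay_g = c(4, 0, 2), az_g = c(0, 0, 2),
      gx_dps = c(3, 0, 1), gy_dps = c(4, 0, 2), gz_dps = c(0, 0, 2)),
    annotations = full_annotation(3 / 16)), class = "triaxial_recording")
  expect_equal(compute_magnitude(rec, "accel")$values, c(5, 0, 3))
  expect_equal(compute_magnitude(rec, "gyro")$values, c(5, 0, 3))
})

test_that("magnitude differencing removes static components exactly", {
  m <- magnitude_series(c(5, 5, 5, 5), "accel", 16)
  expect_equal(magnitude_difference(m)$values, c(0, 0, 0))
  expect_equal(magnitude_difference(magnitude_series(c(1, 3, 2), "accel", 16))$values,
               c(2, -1))
  ramp <- magnitude_series(seq(0, 9, by = 0.5), "gyro", 16)
  expect_equal(magnitude_difference(ramp)$values, rep(0.5, 18))
  # a constant offset vanishes under differencing
  base <- magnitude_series(abs(rnorm(50)), "accel", 16)
  offset <- magnitude_series(base$values + 1, "accel", 16)
  expect_equal(magnitude_difference(offset)$values, magnitude_difference(base)$values)
  expect_error(magnitude_difference(magnitude_series(1, "accel", 16)), "length")
})

test_that("window segmentation matches the enumeration oracle", {
  # single fully annotated 70 s bout: 1120 differenced samples -> 19 windows
  a <- make_diff_series(1120); g <- make_diff_series(1120, seed = 2)
  w <- segment_windows(a, g, full_annotation(71))
  expect_equal(nrow(w), 19)
  expect_equal(oracle_window_count(1120), 19L)

  # boundary: exactly one window
  a1 <- make_diff_series(112); g1 <- make_diff_series(112, seed = 3)
  expect_equal(nrow(segment_windows(a1, g1, full_annotation(8))), 1)

  # window longer than the series: empty result, not an error
  a0 <- make_diff_series(100); g0 <- make_diff_series(100, seed = 4)
  expect_equal(nrow(segment_windows(a0, g0, full_annotation(8))), 0)

  # property: counts match the oracle over random lengths
  set.seed(99)
  for (n in sample.int(10000, 25)) {
    an <- make_diff_series(n, seed = n); gn <- make_diff_series(n, seed = n + 1)
    expect_equal(nrow(segment_windows(an, gn, full_annotation(n / 16 + 1))),
                 oracle_window_count(n))
  }
})

test_that("consecutive windows overlap by exactly 56 samples", {
  a <- make_diff_series(300); g <- make_diff_series(300, seed = 5)
  w <- segment_windows(a, g, full_annotation(20))
  expect_equal(w$accel_diff[[1]][57:112], w$accel_diff[[2]][1:56])
  expect_equal(w$gyro_diff[[2]][57:112], w$gyro_diff[[3]][1:56])
  expect_equal(length(w$accel_diff[[1]]), 112)
})

test_that("windows take the majority activity and sub-majority windows are dropped", {
  rec <- small_flock(seed = 12, duration = 200, n_lame = 1, n_nonlame = 0)[[1]]
  am <- compute_magnitude(rec, "accel"); gm <- compute_magnitude(rec, "gyro")
  w <- segment_windows(magnitude_difference(am), magnitude_difference(gm),
                       rec$annotations)
  fs <- rec$sampling_rate
  ann <- rec$annotations
  for (i in seq_len(nrow(w))) {
    t0 <- w$start_s[i]
    t_samp <- t0 + (0:111) / fs
    labs <- vapply(t_samp, function(t) {
      hit <- which(ann$start_s <= t + 1e-12 & t < ann$end_s + 1e-12)
      if (length(hit)) ann$activity[hit[1]] else NA_character_
    }, character(1))
    tab <- table(labs)
    expect_gte(max(tab), 56)
    expect_equal(w$activity[i], names(tab)[which.max(tab)])
  }
  # lameness label is per recording
  expect_true(all(w$lame == (rec$lameness_score >= 2)))

  # a 50/50 tie between two activities is discarded
  ann2 <- tibble::tibble(sheep_id = "s1", start_s = c(0, 3.5),
                         end_s = c(3.5, 7.0), activity = c("walking", "standing"),
                         lameness_score = 0L)
  a <- make_diff_series(112); g <- make_diff_series(112, seed = 6)
  expect_equal(nrow(segment_windows(a, g, ann2)), 0)
})

test_that("all-zero sensor windows are flagged and removed, others retained", {
  rec <- small_flock(seed = 13, duration = 120, n_lame = 1, n_nonlame = 0)[[1]]
  # zero out the accelerometer for an aligned window-sized stretch
  span <- 113:225
  rec$sensors[span, c("ax_g", "ay_g", "az_g")] <- 0
  am <- compute_magnitude(rec, "accel"); gm <- compute_magnitude(rec, "gyro")
  w <- segment_windows(magnitude_difference(am), magnitude_difference(gm),
                       rec$annotations, accel_mag = am, gyro_mag = gm)
  expect_true(any(w$accel_src_zero))
  kept <- remove_erroneous(w)
  expect_false(any(kept$accel_src_zero))
  expect_equal(nrow(kept), nrow(w) - sum(w$accel_src_zero))
  expect_identical(kept$window_index, w$window_index[!w$accel_src_zero])

  # a single zero sample does not flag the window
  rec2 <- small_flock(seed = 13, duration = 120, n_lame = 1, n_nonlame = 0)[[1]]
  rec2$sensors[50, c("ax_g", "ay_g", "az_g")] <- 0
  w2 <- preprocess_recording(rec2)
  expect_false(any(w2$accel_src_zero))
  expect_identical(remove_erroneous(w2), w2)
})
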