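#' Simulate a flock of annotated sheep-day recordings
#'
#' Generates one [triaxial recording][read_recording] per profile row:
#' an alternating sequence of walking/standing/lying bouts whose realised
#' time shares track each sheep's activity budget, with lameness-dependent
#' signal structure injected by [generate_activity_bout()]. Identical
#' config + profiles + seed reproduce the flock exactly.
#'
#' @param config A [sim_config()].
#' @param profiles Tibble of sheep profiles ([sheep_profiles()]); one
#'   recording is generated per row.
#' @return A list of `triaxial_recording` objects. Each holds `sheep_id`,
#'   `sampling_rate`, a `sensors` tibble
#'   (`timestamp_s, ax_g, ay_g, az_g, gx_dps, gy_dps, gz_dps`) and an
#'   `annotations` tibble (`sheep_id, start_s, end_s, activity,
#'   lameness_score`).
#' @examples
#' cfg <- sim_config(recording_duration = 120, n_lame = 1, n_nonlame = 1, rng_seed = 3)
#' flock <- simulate_flock(cfg, sheep_profiles(cfg))
#' length(flock)
#' @export
simulate_flock <- function(config, profiles = sheep_profiles(config)) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.data.frame(profiles) || nrow(profiles) == 0) {
    stop_ovi("`profiles` must be a non-empty data frame of sheep profiles")
  }
  set.seed(config$rng_seed)
  lapply(seq_len(nrow(profiles)), function(i) {
    simulate_recording(config, profiles[i, ])
  })
}

#' @rdname simulate_flock
#' @param profile A single profile row.
#' @export
simulate_recording <- function(config, profile) {
  validate_profile(profile)
  fs <- config$sampling_rate
  sched <- schedule_bouts(config, profile)
  segs <- vector("list", nrow(sched))
  for (j in seq_len(nrow(sched))) {
    segs[[j]] <- generate_activity_bout(sched$activity[j], profile,
                                        sched$end_s[j] - sched$start_s[j], config)
  }
  sig <- do.call(rbind, segs)
  n <- nrow(sig)
  rec <- list(
    sheep_id = profile$sheep_id,
    sampling_rate = fs,
    lameness_score = profile$lameness_score,
    sensors = tibble(
      timestamp_s = (seq_len(n) - 1) / fs,
      ax_g = sig[, "ax"], ay_g = sig[, "ay"], az_g = sig[, "az"],
      gx_dps = sig[, "gx"], gy_dps = sig[, "gy"], gz_dps = sig[, "gz"]
    ),
    annotations = tibble(
      sheep_id = profile$sheep_id,
      start_s = sched$start_s,
      end_s = sched$end_s,
      activity = sched$activity,
      lameness_score = as.integer(profile$lameness_score)
    )
  )
  class(rec) <- "triaxial_recording"
  rec
}

# Greedy quota scheduler: each new bout takes the activity with the largest
# time deficit against its budget share, with a uniformly drawn bout length.
# Realised shares therefore track the budget to within one maximum bout
# length over the recording.
schedule_bouts <- function(config, profile) {
  fs <- config$sampling_rate
  total <- config$recording_duration
  budget <- c(walking = profile$budget_walking,
              standing = profile$budget_standing,
              lying = profile$budget_lying)
  spent <- c(walking = 0, standing = 0, lying = 0)
  rows <- list()
  t <- 0
  while (t < total - 1e-9) {
    deficit <- budget * (t + 1) - spent
    act <- names(which.max(deficit))
    r <- config$bout_duration_range[[act]]
    len <- runif(1, r[1], r[2])
    len <- min(len, total - t)
    # keep walking bouts at or above the 2 s ethogram minimum
    if (act == "walking" && len < 2) act <- "standing"
    n_samp <- max(1L, round(len * fs))
    len <- n_samp / fs
    rows[[length(rows) + 1]] <- tibble(start_s = t, end_s = t + len, activity = act)
    spent[act] <- spent[act] + len
    t <- t + len
  }
  out <- bind_rows(rows)
  # re-derive exact boundaries from cumulative sample counts
  ns <- round((out$end_s - out$start_s) * fs)
  ends <- cumsum(ns) / fs
  out$start_s <- c(0, head(ends, -1))
  out$end_s <- ends
  out
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf("<triaxial_recording> %s: %d samples at %g Hz, %d bouts, score %d\n",
              x$sheep_id, nrow(x$sensors), x$sampling_rate,
              nrow(x$annotations), x$lameness_score))
  invisible(x)
}
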