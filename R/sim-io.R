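#' Read and write annotated IMU recordings as CSV
#'
#' A recording is stored as two plain-text files: a sensor CSV with header
#' `timestamp_s,ax_g,ay_g,az_g,gx_dps,gy_dps,gz_dps` (one row per sample) and
#' an annotation CSV with header `sheep_id,start_s,end_s,activity,
#' lameness_score`. Doubles round-trip at full precision, so
#' write-then-read reproduces a recording exactly. Annotation rows stored out
#' of order are accepted and sorted by start time; overlapping intervals,
#' intervals with `end < start` and non-monotone sensor timestamps are
#' rejected with row-level diagnostics.
#'
#' @param recording A `triaxial_recording` (see [simulate_flock()]).
#' @param sensor_path,annotation_path File paths for the two CSVs.
#' @return `write_recording()` returns the paths invisibly;
#'   `read_recording()` returns a `triaxial_recording`.
#' @examples
#' cfg <- sim_config(recording_duration = 60, n_lame = 1, n_nonlame = 0, rng_seed = 2)
#' rec <- simulate_flock(cfg, sheep_profiles(cfg))[[1]]
#' sp <- tempfile(fileext = ".csv"); ap <- tempfile(fileext = ".csv")
#' write_recording(rec, sp, ap)
#' rec2 <- read_recording(sp, ap)
#' identical(rec$sensors, rec2$sensors)
#' @export
write_recording <- function(recording, sensor_path, annotation_path) {
  stopifnot(inherits(recording, "triaxial_recording"))
  readr::write_csv(recording$sensors, sensor_path)
  readr::write_csv(recording$annotations, annotation_path)
  invisible(c(sensor_path, annotation_path))
}

#' @rdname write_recording
#' @export
read_recording <- function(sensor_path, annotation_path) {
  sens_cols <- readr::cols(
    timestamp_s = readr::col_double(), ax_g = readr::col_double(),
    ay_g = readr::col_double(), az_g = readr::col_double(),
    gx_dps = readr::col_double(), gy_dps = readr::col_double(),
    gz_dps = readr::col_double()
  )
  sensors <- readr::read_csv(sensor_path, col_types = sens_cols, progress = FALSE)
  expected <- c("timestamp_s", "ax_g", "ay_g", "az_g", "gx_dps", "gy_dps", "gz_dps")
  if (!identical(names(sensors), expected)) {
    stop_ovi("malformed sensor CSV %s: expected columns %s", sensor_path,
             paste(expected, collapse = ","))
  }
  if (anyNA(sensors)) {
    bad <- which(rowSums(is.na(sensors)) > 0)[1]
    stop_ovi("malformed sensor CSV %s: missing values at row %d", sensor_path, bad)
  }
  dt <- diff(sensors$timestamp_s)
  if (length(dt) && any(dt <= 0)) {
    stop_ovi("non-monotone timestamps in %s at row %d", sensor_path, which(dt <= 0)[1] + 1)
  }
  if (length(dt) > 1 && diff(range(dt)) > 1e-6) {
    stop_ovi("irregular sampling in %s: timestamp steps vary by more than 1e-6 s", sensor_path)
  }
  ann_cols <- readr::cols(
    sheep_id = readr::col_character(), start_s = readr::col_double(),
    end_s = readr::col_double(), activity = readr::col_character(),
    lameness_score = readr::col_integer()
  )
  ann <- readr::read_csv(annotation_path, col_types = ann_cols, progress = FALSE)
  if (!identical(names(ann), c("sheep_id", "start_s", "end_s", "activity", "lameness_score"))) {
    stop_ovi("malformed annotation CSV %s", annotation_path)
  }
  bad_len <- which(ann$end_s < ann$start_s)
  if (length(bad_len)) {
    stop_ovi("annotation row %d in %s has end_s < start_s", bad_len[1], annotation_path)
  }
  bad_act <- which(!ann$activity %in% ACTIVITIES)
  if (length(bad_act)) {
    stop_ovi("annotation row %d in %s has unknown activity '%s'",
             bad_act[1], annotation_path, ann$activity[bad_act[1]])
  }
  ann <- arrange(ann, .data$start_s)
  if (nrow(ann) > 1) {
    overlap <- which(ann$start_s[-1] < ann$end_s[-nrow(ann)] - 1e-9)
    if (length(overlap)) {
      stop_ovi("annotations %d and %d in %s overlap", overlap[1], overlap[1] + 1,
               annotation_path)
    }
  }
  fs <- if (length(dt)) 1 / stats::median(dt) else NA_real_
  rec <- list(
    sheep_id = ann$sheep_id[1] %||% NA_character_,
    sampling_rate = fs,
    lameness_score = ann$lameness_score[1],
    sensors = sensors,
    annotations = ann
  )
  class(rec) <- "triaxial_recording"
  rec
}
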