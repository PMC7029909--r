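#' Run the full lameness-detection pipeline
#'
#' Orchestrates simulate -> preprocess -> extract features -> rank (ReliefF
#' per activity) -> cross-validated classification per activity ->
#' sheep-level evaluation, as one reproducible run. All stage seeds derive
#' from the single `rng_seed` in `config` by fixed offsets. When `out_dir`
#' is given, every stage output is written as CSV/JSON-free plain text along
#' with a manifest of file digests; re-running with the same inputs
#' reproduces identical digests.
#'
#' @param config A [sim_config()].
#' @param profiles Sheep profiles (default [sheep_profiles()] of `config`).
#' @param algorithms Character vector of [classifier_spec()] algorithms to
#'   bench (default `"rf"`).
#' @param n_features Number of top-ranked features per activity model
#'   (default: all 32).
#' @param k Cross-validation folds (default 10).
#' @param out_dir Optional directory for stage outputs and the run manifest.
#' @return List of class `ovisense_run`: `config`, `profiles`, `windows`
#'   (row counts only when `keep_windows = FALSE`), `features`, `rankings`,
#'   `cv` (nested list activity -> algorithm -> `cv_result`), `sheep_level`
#'   (activity -> [sheep_level_evaluation()] output) and `log` (per-stage
#'   row counts).
#' @param keep_windows Keep the raw window tibble in the result (can be
#'   large).
#' @export
run_pipeline <- function(config, profiles = sheep_profiles(config),
                         algorithms = "rf", n_features = NULL, k = 10,
                         out_dir = NULL, keep_windows = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_lame == 0 || config$n_nonlame == 0) {
    stop_ovi("evaluation needs both groups: empty %s group in config",
             if (config$n_lame == 0) "lame" else "non-lame")
  }
  log <- list()
  flock <- simulate_flock(config, profiles)
  log$recordings <- length(flock)

  windows <- preprocess_flock(flock)
  log$windows_retained <- nrow(windows)

  features <- extract_features(windows, f_s = config$sampling_rate)
  log$features_extracted <- nrow(features)

  rankings <- lapply(ACTIVITIES, function(a) {
    relieff_rank(features[features$activity == a, , drop = FALSE],
                 seed = config$rng_seed + 11L, activity = a)
  })
  names(rankings) <- ACTIVITIES

  cv <- lapply(ACTIVITIES, function(a) {
    sub <- features[features$activity == a, , drop = FALSE]
    res <- lapply(algorithms, function(alg) {
      spec <- classifier_spec(alg, seed = config$rng_seed + 23L)
      run_cv(sub, spec, ranking = rankings[[a]],
             n_features = n_features %||% nrow(rankings[[a]]), k = k)
    })
    names(res) <- algorithms
    res
  })
  names(cv) <- ACTIVITIES

  sheep_level <- lapply(ACTIVITIES, function(a) {
    sheep_level_evaluation(cv[[a]][[algorithms[1]]])
  })
  names(sheep_level) <- ACTIVITIES

  run <- structure(list(config = config, profiles = profiles,
                        windows = if (keep_windows) windows else NULL,
                        features = features, rankings = rankings, cv = cv,
                        sheep_level = sheep_level, log = log),
                   class = "ovisense_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# persist stage outputs + digest manifest
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$features, file.path(out_dir, "features.csv"))
  rk <- purrr::map_dfr(run$rankings, ~ as_tibble(.x))
  readr::write_csv(rk[, c("activity", "rank", "feature", "weight")],
                   file.path(out_dir, "rankings.csv"))
  preds <- purrr::map_dfr(run$cv, function(by_alg) {
    purrr::map_dfr(by_alg, function(r) {
      mutate(r$predictions, algorithm = r$algorithm)
    })
  })
  readr::write_csv(preds, file.path(out_dir, "predictions.csv"))
  verdicts <- purrr::map_dfr(names(run$sheep_level), function(a) {
    mutate(run$sheep_level[[a]]$verdicts, activity = a)
  })
  readr::write_csv(verdicts, file.path(out_dir, "sheep_verdicts.csv"))
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)),
                     seed = run$config$rng_seed)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(out_dir)
}

#' Summarise a pipeline run
#'
#' Produces the human-readable reporting tables of a completed run: window
#' counts and within-behaviour lameness ratios, top-10 feature rankings per
#' activity, mean CV metrics per activity and algorithm, and the sheep-level
#' summary (delta-sigma, threshold, Mann-Whitney p, sheep accuracy). Pure
#' function of the run object: regeneration is idempotent.
#'
#' @param run An `ovisense_run` from [run_pipeline()].
#' @return List of tibbles: `counts`, `rankings_top10`, `cv_metrics`,
#'   `sheep_level`.
#' @export
summarize_run <- function(run) {
  stopifnot(inherits(run, "ovisense_run"))
  counts <- run$features |>
    count(.data$activity, lameness = ifelse(.data$lame, "lame", "non-lame"),
          name = "n_windows") |>
    group_by(.data$activity) |>
    mutate(pct_within_behaviour = 100 * .data$n_windows / sum(.data$n_windows)) |>
    ungroup()
  rankings_top10 <- purrr::map_dfr(run$rankings, function(r) {
    as_tibble(r)[seq_len(min(10, nrow(r))), c("activity", "rank", "feature", "weight")]
  })
  cv_metrics <- purrr::map_dfr(run$cv, function(by_alg) {
    purrr::map_dfr(by_alg, function(r) {
      tibble(activity = r$activity, algorithm = r$algorithm,
             n_features = r$n_features, !!!r$mean_metrics)
    })
  })
  sheep_level <- purrr::map_dfr(names(run$sheep_level), function(a) {
    s <- run$sheep_level[[a]]
    tibble(activity = a,
           delta_sigma = s$separation$delta_sigma,
           threshold = s$separation$threshold,
           mann_whitney_p = s$separation$p_value,
           sheep_accuracy_pct = s$accuracy_pct)
  })
  list(counts = counts, rankings_top10 = rankings_top10,
       cv_metrics = cv_metrics, sheep_level = sheep_level)
}

#' @export
print.ovisense_run <- function(x, ...) {
  cat(sprintf("<ovisense_run> %d recordings, %d windows, %d features rows; seed %d\n",
              x$log$recordings, x$log$windows_retained, x$log$features_extracted,
              x$config$rng_seed))
  invisible(x)
}
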