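#' Lameness-stratified k-fold assignment
#'
#' Partitions windows into `k` folds stratified on the binary lameness class
#' only (each fold's class proportion is within one window of the global
#' proportion). Stratification deliberately ignores sheep identity, matching
#' the study design; see [run_cv()]'s `group` argument for the
#' grouped-by-sheep alternative.
#'
#' @param labels Logical lameness labels, one per window.
#' @param k Number of folds (default 10); every class must have >= k members.
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return Integer vector of fold ids in `1..k`, one per window.
#' @examples
#' f <- stratified_kfold(rep(c(TRUE, FALSE), c(60, 40)), k = 10, seed = 1)
#' table(f)
#' @export
stratified_kfold <- function(labels, k = 10, seed = 1L) {
  labels <- as.logical(labels)
  cnt <- table(labels)
  if (length(cnt) < 2 || any(cnt < k)) {
    stop_ovi("each class needs >= %d windows for %d-fold CV (got %s)",
             k, k, paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "))
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in c(FALSE, TRUE)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated lameness classification within one activity
#'
#' Trains the specified classifier on nine folds and predicts the held-out
#' fold, for all ten rotations, using only the `n_features` top-ranked
#' feature columns. No test window is seen in training within a fold. Note
#' that with the default lameness-only stratification, windows of the same
#' sheep appear on both sides of each split (sheep-level leakage, as in the
#' study design); pass `group = "sheep_id"` for grouped-by-sheep folds.
#'
#' @param feature_table Feature tibble ([extract_features()]) restricted to
#'   one activity, with a logical `lame` column.
#' @param spec A [classifier_spec()].
#' @param ranking Optional `ranked_features` from [relieff_rank()]; required
#'   when `n_features` is less than the full set.
#' @param n_features Number of top-ranked features to use (1-32). Default:
#'   all available.
#' @param k Number of folds (default 10).
#' @param folds Optional precomputed fold assignment (reused across a
#'   feature sweep).
#' @param group Optional column name for grouped CV: folds then partition
#'   the groups (e.g. sheep) rather than windows.
#' @return A `cv_result`: list with `algorithm`, `activity`, `n_features`,
#'   per-fold confusion counts and metrics, mean metrics, and out-of-fold
#'   predictions (one per window).
#' @export
run_cv <- function(feature_table, spec, ranking = NULL, n_features = NULL,
                   k = 10, folds = NULL, group = NULL) {
  stopifnot(is.data.frame(feature_table), inherits(spec, "classifier_spec"))
  avail <- intersect(feature_names("both"), names(feature_table))
  if (!is.null(ranking)) {
    missing <- setdiff(ranking$feature, names(feature_table))
    if (length(missing)) {
      stop_ovi("ranking names features absent from the table: %s",
               paste(missing, collapse = ", "))
    }
    # canonical column order: the model sees a feature SET, so any two
    # rankings selecting the same set give identical results
    use <- intersect(avail, top_k(ranking, n_features %||% nrow(ranking)))
  } else {
    if (!is.null(n_features) && n_features < length(avail)) {
      stop_ovi("`n_features` < full set requires a `ranking`")
    }
    use <- avail
  }
  y <- as.logical(feature_table$lame)
  X <- as.matrix(feature_table[, use, drop = FALSE])
  if (is.null(folds)) {
    if (is.null(group)) {
      folds <- stratified_kfold(y, k = k, seed = spec$seed)
    } else {
      folds <- grouped_kfold(feature_table[[group]], labels = y, k = k, seed = spec$seed)
    }
  }
  k <- max(folds)

  fold_rows <- vector("list", k)
  preds <- rep(NA, length(y))
  for (f in seq_len(k)) {
    te <- folds == f
    set.seed(spec$seed + 1000L * f)
    fit <- fit_classifier(spec, X[!te, , drop = FALSE], y[!te])
    p <- predict_classifier(fit, X[te, , drop = FALSE])
    preds[te] <- p
    fold_rows[[f]] <- tibble(
      fold = f,
      tp = sum(p & y[te]), tn = sum(!p & !y[te]),
      fp = sum(p & !y[te]), fn = sum(!p & y[te])
    )
  }
  confusion <- bind_rows(fold_rows)
  fold_metrics <- bind_cols(confusion["fold"], compute_metrics(confusion))
  mean_metrics <- colMeans(fold_metrics[, c("overall_accuracy", "precision",
                                            "recall", "f_score", "specificity")])
  activity <- if (length(unique(feature_table$activity)) == 1) {
    feature_table$activity[1]
  } else NA_character_
  structure(list(
    algorithm = spec$algorithm,
    activity = activity,
    n_features = length(use),
    features = use,
    folds = folds,
    confusion = confusion,
    fold_metrics = fold_metrics,
    mean_metrics = as.list(mean_metrics),
    predictions = tibble(
      sheep_id = feature_table$sheep_id %||% NA_character_,
      window_index = feature_table$window_index %||% seq_along(y),
      activity = feature_table$activity %||% activity,
      fold = folds,
      lame = y,
      predicted_lame = as.logical(preds)
    )
  ), class = "cv_result")
}

# grouped k-fold: groups (sheep) are dealt into folds, stratified on the
# group-level class so every training set keeps the global class balance
# (otherwise holding out a lame sheep depletes the lame class and the
# classifier drifts toward the opposite label at the null)
grouped_kfold <- function(groups, labels = NULL, k = 10, seed = 1L) {
  u <- unique(groups)
  if (length(u) < k) stop_ovi("need >= %d groups for %d-fold grouped CV", k, k)
  set.seed(seed)
  gf <- integer(length(u))
  if (is.null(labels)) {
    gf <- rep_len(seq_len(k), length(u))[sample.int(length(u))]
  } else {
    glab <- as.logical(labels[match(u, groups)])
    for (cl in unique(glab)) {
      idx <- which(glab == cl)
      idx <- idx[sample.int(length(idx))]
      gf[idx] <- rep_len(sample.int(k), length(idx))
    }
  }
  gf[match(groups, u)]
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s on %s: %d features, %d folds, accuracy %.4f\n",
              x$algorithm, x$activity %||% "?", x$n_features,
              nrow(x$confusion), x$mean_metrics$overall_accuracy))
  invisible(x)
}

#' Sweep the number of top-ranked features
#'
#' Runs [run_cv()] for each value of `n_features`, reusing a single fold
#' assignment across the sweep so that curves differ only in the feature
#' set.
#'
#' @inheritParams run_cv
#' @param n_features Integer vector of feature counts (default 1 to the
#'   number of ranked features).
#' @return A `cv_sweep`: list with `curve` (tibble of mean metrics per
#'   feature count) and `results` (the underlying `cv_result` list).
#' @export
feature_sweep <- function(feature_table, ranking, spec,
                          n_features = seq_len(nrow(ranking)), k = 10,
                          folds = NULL) {
  if (is.null(folds)) {
    folds <- stratified_kfold(as.logical(feature_table$lame), k = k, seed = spec$seed)
  }
  results <- lapply(n_features, function(nf) {
    run_cv(feature_table, spec, ranking = ranking, n_features = nf, folds = folds)
  })
  curve <- purrr::map2_dfr(results, n_features, function(r, nf) {
    tibble(algorithm = r$algorithm, activity = r$activity, n_features = nf,
           !!!r$mean_metrics)
  })
  structure(list(curve = curve, results = results, folds = folds),
            class = "cv_sweep")
}

#' @export
print.cv_sweep <- function(x, ...) {
  best <- x$curve[which.max(x$curve$overall_accuracy), ]
  cat(sprintf("<cv_sweep> %s on %s: %d feature counts; best accuracy %.4f at %d features\n",
              best$algorithm, best$activity %||% "?", nrow(x$curve),
              best$overall_accuracy, best$n_features))
  invisible(x)
}
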