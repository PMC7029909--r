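#' Two-phase activity-then-lameness prediction
#'
#' `fit_two_phase()` trains the phase-1 activity classifier (the same
#' 32-feature representation, with a random-forest spec by default) on
#' activity labels, and one phase-2 lameness classifier per activity.
#' `predict_two_phase()` routes each window to the lameness model matching
#' its predicted activity; with `oracle_activity = TRUE` the ground-truth
#' activity is used for routing instead, in which case the output equals the
#' within-activity model's prediction.
#'
#' @param feature_table Feature tibble with `activity` and `lame` columns.
#' @param lameness_spec A [classifier_spec()] for the per-activity lameness
#'   models.
#' @param activity_spec A [classifier_spec()] for the phase-1 activity model
#'   (default: random forest with the same seed).
#' @param features Feature columns to use (default: all 32 present).
#' @return `fit_two_phase()`: a `two_phase_model`. `predict_two_phase()`:
#'   tibble with `predicted_activity` and `predicted_lame` per window.
#' @examples
#' \donttest{
#' cfg <- sim_config(recording_duration = 400, n_lame = 2, n_nonlame = 2, rng_seed = 9)
#' feats <- extract_features(preprocess_flock(simulate_flock(cfg, sheep_profiles(cfg, 2))))
#' mod <- fit_two_phase(feats, classifier_spec("rf", 1))
#' head(predict_two_phase(mod, feats))
#' }
#' @export
fit_two_phase <- function(feature_table, lameness_spec,
                          activity_spec = classifier_spec("rf", seed = lameness_spec$seed),
                          features = NULL) {
  stopifnot(is.data.frame(feature_table), inherits(lameness_spec, "classifier_spec"))
  features <- features %||% intersect(feature_names("both"), names(feature_table))
  X <- as.matrix(feature_table[, features, drop = FALSE])
  acts <- sort(unique(feature_table$activity))
  set.seed(activity_spec$seed)
  activity_model <- randomForest::randomForest(
    x = X, y = factor(feature_table$activity, levels = acts),
    ntree = activity_spec$hyperparameters$n_trees %||% 250L,
    nodesize = activity_spec$hyperparameters$min_leaf %||% 1L,
    mtry = max(1L, floor(sqrt(ncol(X)))))
  lameness_models <- lapply(acts, function(a) {
    sub <- feature_table$activity == a
    set.seed(lameness_spec$seed + match(a, acts))
    fit_classifier(lameness_spec, X[sub, , drop = FALSE],
                   as.logical(feature_table$lame[sub]))
  })
  names(lameness_models) <- acts
  structure(list(activity_model = activity_model,
                 lameness_models = lameness_models,
                 features = features, activities = acts),
            class = "two_phase_model")
}

#' @rdname fit_two_phase
#' @param model A `two_phase_model`.
#' @param newdata Feature tibble of windows to predict.
#' @param oracle_activity Use the table's ground-truth `activity` column for
#'   routing instead of the phase-1 prediction.
#' @export
predict_two_phase <- function(model, newdata, oracle_activity = FALSE) {
  stopifnot(inherits(model, "two_phase_model"), is.data.frame(newdata))
  X <- as.matrix(newdata[, model$features, drop = FALSE])
  act <- if (oracle_activity) {
    as.character(newdata$activity)
  } else {
    as.character(predict(model$activity_model, X))
  }
  missing <- setdiff(unique(act), names(model$lameness_models))
  if (length(missing)) {
    stop_ovi("no lameness model for predicted activity: %s",
             paste(missing, collapse = ", "))
  }
  lame_pred <- rep(NA, nrow(X))
  for (a in unique(act)) {
    idx <- act == a
    lame_pred[idx] <- predict_classifier(model$lameness_models[[a]],
                                         X[idx, , drop = FALSE])
  }
  tibble(predicted_activity = act, predicted_lame = as.logical(lame_pred))
}
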