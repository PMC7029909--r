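test_that("stratified folds balance the lameness class to within one window", {
  y <- rep(c(TRUE, FALSE), c(60, 40))
  f <- stratified_kfold(y, k = 10, seed = 1)
  expect_setequal(unique(f), 1:10)
  expect_length(f, 100)
  for (k in 1:10) {
    expect_equal(sum(y[f == k]), 6)
    expect_equal(sum(!y[f == k]), 4)
  }
  expect_identical(stratified_kfold(y, k = 10, seed = 1), f)
  expect_false(identical(stratified_kfold(y, k = 10, seed = 2), f))
  expect_error(stratified_kfold(rep(c(TRUE, FALSE), c(5, 95)), k = 10),
               "each class needs")
})

test_that("cross-validation is sane on separable data and covers every window once", {
  tab <- synthetic_table(200, informative = 0, noise_cols = 3)
  tab$accel_mean <- as.numeric(tab$lame)       # perfectly separating feature
  r <- run_cv(tab, classifier_spec("rf", seed = 3))
  expect_gte(r$mean_metrics$overall_accuracy, 0.99)
  # confusion counts partition the subset
  expect_equal(sum(r$confusion$tp + r$confusion$tn + r$confusion$fp + r$confusion$fn),
               nrow(tab))
  # one out-of-fold prediction per window
  expect_false(anyNA(r$predictions$predicted_lame))
  expect_equal(nrow(r$predictions), nrow(tab))
  expect_setequal(r$predictions$window_index, tab$window_index)
  # mean metrics are the fold averages
  expect_equal(r$mean_metrics$overall_accuracy, mean(r$fold_metrics$overall_accuracy))
})

test_that("label permutation drives accuracy to chance", {
  tab <- synthetic_table(600, informative = 2, noise_cols = 4, seed = 31)
  set.seed(77)
  tab$lame <- sample(tab$lame)
  for (alg in c("rf", "knn")) {
    r <- run_cv(tab, classifier_spec(alg, seed = 5))
    expect_gt(r$mean_metrics$overall_accuracy, 0.40)
    expect_lt(r$mean_metrics$overall_accuracy, 0.60)
  }
})

test_that("the full feature set is invariant to ranking order", {
  tab <- synthetic_table(150, informative = 2, noise_cols = 30, seed = 41)
  r <- relieff_rank(tab, k_neighbors = 5)
  rev_rank <- r[rev(seq_len(nrow(r))), ]
  class(rev_rank) <- class(r)
  attr(rev_rank, "params") <- attr(r, "params")
  folds <- stratified_kfold(tab$lame, k = 5, seed = 9)
  a <- run_cv(tab, classifier_spec("rf", seed = 9), ranking = r,
              n_features = 32, folds = folds)
  b <- run_cv(tab, classifier_spec("rf", seed = 9), ranking = rev_rank,
              n_features = 32, folds = folds)
  expect_equal(a$predictions, b$predictions)
  expect_error(run_cv(tab, classifier_spec("rf"), ranking = {
    bad <- r; bad$feature[1] <- "no_such_feature"; bad
  }), "absent from the table")
})

test_that("every algorithm trains, predicts and is reproducible", {
  tab <- synthetic_table(240, informative = 3, noise_cols = 5, seed = 51)
  for (alg in c("rf", "nn", "svm", "ada", "knn")) {
    r1 <- run_cv(tab, classifier_spec(alg, seed = 13), k = 5)
    r2 <- run_cv(tab, classifier_spec(alg, seed = 13), k = 5)
    expect_equal(r1$predictions, r2$predictions)
    # informative features make all algorithms beat chance comfortably
    expect_gt(r1$mean_metrics$overall_accuracy, 0.7)
  }
})

test_that("the feature sweep reuses folds and finds the informative subset", {
  tab <- synthetic_table(300, informative = 3, noise_cols = 29, seed = 61)
  r <- relieff_rank(tab, k_neighbors = 7)
  expect_setequal(top_k(r, 3), feature_names("both")[1:3])
  sw <- feature_sweep(tab, r, classifier_spec("knn", seed = 21), n_features = c(1, 3, 32))
  expect_equal(nrow(sw$curve), 3)
  acc3 <- sw$curve$overall_accuracy[sw$curve$n_features == 3]
  acc32 <- sw$curve$overall_accuracy[sw$curve$n_features == 32]
  expect_lt(abs(acc3 - acc32), 0.05)
  sw2 <- feature_sweep(tab, r, classifier_spec("knn", seed = 21), n_features = c(1, 3, 32))
  expect_equal(sw$curve, sw2$curve)
  # structural: a full sweep has one entry per feature count
  sw_full <- feature_sweep(tab[1:120, ], r, classifier_spec("knn", seed = 21), k = 5)
  expect_equal(sw_full$curve$n_features, 1:32)
})

test_that("two-phase prediction routes windows to the matching lameness model", {
  f <- extract_features(preprocess_flock(small_flock(effect_size = 2, seed = 71,
                                                     duration = 500,
                                                     n_lame = 3, n_nonlame = 3)))
  mod <- fit_two_phase(f, classifier_spec("rf", seed = 3))
  oracle <- predict_two_phase(mod, f, oracle_activity = TRUE)
  expect_equal(oracle$predicted_activity, f$activity)
  # oracle routing equals the within-activity model's own prediction
  for (a in unique(f$activity)) {
    idx <- f$activity == a
    direct <- ovisense:::predict_classifier(mod$lameness_models[[a]],
                                            as.matrix(f[idx, mod$features]))
    expect_equal(oracle$predicted_lame[idx], direct)
  }
  # end-to-end routing stays close to oracle routing
  auto <- predict_two_phase(mod, f)
  expect_gt(mean(auto$predicted_activity == f$activity), 0.9)
  expect_lt(abs(mean(auto$predicted_lame == f$lame) -
                  mean(oracle$predicted_lame == f$lame)), 0.05)
  # missing per-activity model is rejected
  mod2 <- mod
  mod2$lameness_models$standing <- NULL
  expect_error(predict_two_phase(mod2, f, oracle_activity = TRUE),
               "no lameness model")
})
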