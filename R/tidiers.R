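#' @importFrom generics tidy glance
NULL

#' Tidy a cross-validation result
#'
#' `tidy()` returns per-fold confusion counts and metrics; `glance()` the
#' one-row cross-validated summary (mean metrics across folds).
#'
#' @param x A `cv_result` from [run_cv()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cv_result <- function(x, ...) {
  bind_cols(tibble(algorithm = x$algorithm, activity = x$activity,
                   n_features = x$n_features),
            left_join(x$confusion, x$fold_metrics, by = "fold"))
}

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble(algorithm = x$algorithm, activity = x$activity,
         n_features = x$n_features, folds = nrow(x$confusion),
         !!!x$mean_metrics)
}

#' Tidy a feature ranking
#'
#' @param x A `ranked_features` from [relieff_rank()].
#' @param ... Unused.
#' @return Tibble `activity`, `rank`, `feature`, `weight`.
#' @export
tidy.ranked_features <- function(x, ...) {
  as_tibble(x)[, c("activity", "rank", "feature", "weight")]
}

#' Tidy a sheep-level group separation
#'
#' `tidy()` returns the per-sheep ratio table (when the separation was
#' computed from one); `glance()` the one-row summary with group moments,
#' delta-sigma, threshold and Mann-Whitney test.
#'
#' @param x A `group_separation` from [sigma_difference()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.group_separation <- function(x, ...) {
  if (is.null(x$ratios)) {
    stop_ovi("this group_separation was built from bare ratio vectors; use glance()")
  }
  as_tibble(x$ratios)
}

#' @rdname tidy.group_separation
#' @export
glance.group_separation <- function(x, ...) {
  tibble(mu_lame = x$mu_lame, sigma_lame = x$sigma_lame,
         mu_nonlame = x$mu_nonlame, sigma_nonlame = x$sigma_nonlame,
         delta_sigma = x$delta_sigma, threshold = x$threshold,
         mann_whitney_U = x$mann_whitney_U, p_value = x$p_value,
         n_lame = x$n_lame, n_nonlame = x$n_nonlame)
}

#' Tidy a feature sweep
#'
#' @param x A `cv_sweep` from [feature_sweep()].
#' @param ... Unused.
#' @return The accuracy curve tibble (one row per feature count).
#' @export
tidy.cv_sweep <- function(x, ...) x$curve
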