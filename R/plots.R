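#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline geom_vline labs facet_wrap coord_flip theme_minimal
NULL

#' Plot an accuracy-vs-feature-count sweep
#'
#' Cross-validated overall accuracy as a function of the number of
#' top-ranked features, one line per algorithm/activity present.
#'
#' @param object A `cv_sweep` from [feature_sweep()] or a combined curve
#'   tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_sweep <- function(object, ...) {
  curve <- if (is.data.frame(object)) object else object$curve
  ggplot(curve, aes(x = .data$n_features, y = .data$overall_accuracy,
                    colour = .data$algorithm)) +
    geom_line() + geom_point(size = 1) +
    labs(x = "number of top-ranked features", y = "10-fold CV accuracy",
         colour = "algorithm") +
    theme_minimal()
}

#' Plot ReliefF feature weights
#'
#' Horizontal bar chart of ReliefF weights in rank order (top-ranked at the
#' top).
#'
#' @param object A `ranked_features` from [relieff_rank()].
#' @param top_n How many top features to show (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ranked_features <- function(object, top_n = 10, ...) {
  d <- as_tibble(object)[seq_len(min(top_n, nrow(object))), ]
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot(d, aes(x = .data$feature, y = .data$weight)) +
    geom_col() + coord_flip() +
    labs(x = NULL, y = "ReliefF weight") +
    theme_minimal()
}

#' Plot sheep-level group separation
#'
#' Per-sheep lame-window ratios by true group, with the midpoint decision
#' threshold as a dashed line.
#'
#' @param object A `group_separation` built from a per-sheep ratio table
#'   (e.g. via [sheep_level_evaluation()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_separation <- function(object, ...) {
  if (is.null(object$ratios)) {
    stop_ovi("plotting needs a group_separation built from a ratio table")
  }
  d <- mutate(as_tibble(object$ratios),
              group = ifelse(.data$lame, "lame", "non-lame"))
  ggplot(d, aes(x = .data$group, y = .data$ratio)) +
    geom_point(position = ggplot2::position_jitter(width = 0.08, height = 0),
               alpha = 0.8) +
    geom_hline(yintercept = object$threshold, linetype = "dashed") +
    labs(x = NULL, y = "per-sheep lame-window ratio") +
    theme_minimal()
}
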