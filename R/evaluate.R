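#' Window-level classification metrics
#'
#' Computes overall accuracy, precision, recall (sensitivity), F-score
#' (harmonic mean of precision and recall) and specificity from confusion
#' counts, where the positive class is "lame". A ratio with zero denominator
#' is reported as 0 and flagged in `degenerate`.
#'
#' @param counts Data frame with columns `tp`, `tn`, `fp`, `fn` (one row per
#'   fold or experiment), or a single named vector.
#' @return Tibble with the five metrics plus a `degenerate` flag, one row
#'   per input row.
#' @examples
#' compute_metrics(data.frame(tp = 30, fn = 10, fp = 5, tn = 55))
#' @export
compute_metrics <- function(counts) {
  if (!is.data.frame(counts)) counts <- as_tibble(as.list(counts))
  needed <- c("tp", "tn", "fp", "fn")
  if (!all(needed %in% names(counts))) {
    stop_ovi("counts need columns %s", paste(needed, collapse = ", "))
  }
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, tn, fp, fn) < 0)) stop_ovi("confusion counts must be >= 0")
  total <- tp + tn + fp + fn
  if (any(total == 0)) stop_ovi("all-zero confusion counts at row %d", which(total == 0)[1])
  ratio <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  tibble(
    overall_accuracy = (tp + tn) / total,
    precision = precision,
    recall = recall,
    f_score = ratio(2 * precision * recall, precision + recall),
    specificity = ratio(tn, tn + fp),
    degenerate = (tp + fp == 0) | (tp + fn == 0) | (tn + fp == 0)
  )
}

#' Per-sheep lame-window ratio
#'
#' For each sheep, the fraction of its windows predicted lame (within one
#' activity when the predictions are activity-specific). Invariant to row
#' order; a sheep with zero windows simply does not appear.
#'
#' @param predictions Tibble with `sheep_id`, `predicted_lame` and
#'   (optionally) the true `lame` label, e.g. the `predictions` element of a
#'   [run_cv()] result.
#' @return Tibble `sheep_id`, `n_windows`, `ratio` (in [0, 1]) and, when
#'   available, the sheep's true `lame` status.
#' @export
per_sheep_lame_ratio <- function(predictions) {
  stopifnot(is.data.frame(predictions),
            all(c("sheep_id", "predicted_lame") %in% names(predictions)))
  if (anyNA(predictions$sheep_id)) stop_ovi("every prediction needs a sheep_id")
  out <- predictions |>
    group_by(.data$sheep_id) |>
    summarise(n_windows = n(),
              ratio = mean(.data$predicted_lame),
              .groups = "drop")
  if ("lame" %in% names(predictions)) {
    truth <- predictions |>
      group_by(.data$sheep_id) |>
      summarise(lame = any(.data$lame), .groups = "drop")
    out <- left_join(out, truth, by = "sheep_id")
  }
  out
}

#' Sheep-level group separation (sigma-difference)
#'
#' Summarises how far apart the lame and non-lame groups sit in per-sheep
#' lame-window ratio space:
#' `delta_sigma = (mu_lame - sigma_lame) - (mu_nonlame + sigma_nonlame)`,
#' positive exactly when the two groups' 1-SD intervals do not overlap, and
#' the midpoint decision threshold `(mu_lame + mu_nonlame) / 2`. Group SDs
#' are sample standard deviations (singleton groups have SD 0). A
#' two-sided Mann-Whitney U test compares the two ratio distributions.
#'
#' @param ratios Tibble from [per_sheep_lame_ratio()] with a logical `lame`
#'   column, or use `ratios_lame`/`ratios_nonlame` directly.
#' @param ratios_lame,ratios_nonlame Numeric vectors of per-sheep ratios for
#'   the two groups (alternative interface).
#' @return A `group_separation` object: list with group means/SDs,
#'   `delta_sigma`, `threshold`, `mann_whitney_U`, `p_value`, group sizes
#'   and the per-sheep ratio table.
#' @examples
#' sigma_difference(ratios_lame = c(0.9, 0.7), ratios_nonlame = c(0.3, 0.1))
#' @export
sigma_difference <- function(ratios = NULL, ratios_lame = NULL, ratios_nonlame = NULL) {
  if (!is.null(ratios)) {
    stopifnot(is.data.frame(ratios), all(c("ratio", "lame") %in% names(ratios)))
    ratios_lame <- ratios$ratio[ratios$lame]
    ratios_nonlame <- ratios$ratio[!ratios$lame]
  }
  if (length(ratios_lame) < 1 || length(ratios_nonlame) < 1) {
    stop_ovi("both groups need at least one sheep (got %d lame, %d non-lame)",
             length(ratios_lame), length(ratios_nonlame))
  }
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  mu_l <- mean(ratios_lame); sd_l <- sd0(ratios_lame)
  mu_n <- mean(ratios_nonlame); sd_n <- sd0(ratios_nonlame)
  mw <- mann_whitney(ratios_lame, ratios_nonlame)
  structure(list(
    mu_lame = mu_l, sigma_lame = sd_l,
    mu_nonlame = mu_n, sigma_nonlame = sd_n,
    delta_sigma = (mu_l - sd_l) - (mu_n + sd_n),
    threshold = (mu_l + mu_n) / 2,
    mann_whitney_U = mw[["U"]],
    p_value = mw[["p_value"]],
    n_lame = length(ratios_lame), n_nonlame = length(ratios_nonlame),
    ratios = ratios
  ), class = "group_separation")
}

#' @export
print.group_separation <- function(x, ...) {
  cat(sprintf(paste0("<group_separation> delta_sigma %.4f, threshold %.4f ",
                     "(lame %.3f+/-%.3f, non-lame %.3f+/-%.3f), U %.1f, p %.4g\n"),
              x$delta_sigma, x$threshold, x$mu_lame, x$sigma_lame,
              x$mu_nonlame, x$sigma_nonlame, x$mann_whitney_U, x$p_value))
  invisible(x)
}

#' Mann-Whitney U test for two ratio groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test: exact p-value when the
#' combined sample is small (<= 20) and untied, normal approximation with
#' tie correction otherwise. `U` counts pairs won by the first group. When
#' every value in both groups is identical the test carries no evidence and
#' p = 1.
#'
#' @param x,y Numeric vectors (the lame and non-lame group ratios).
#' @return Named vector `c(U = ..., p_value = ...)`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U 0, p 0.1
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop_ovi("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1) {
    return(c(U = length(x) * length(y) / 2, p_value = 1))
  }
  exact <- (length(x) + length(y)) <= 20 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  c(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Classify sheep against the midpoint threshold
#'
#' A sheep is declared lame when its lame-window ratio strictly exceeds the
#' threshold; sheep-level accuracy is the percentage of correct verdicts.
#'
#' @param ratios Tibble from [per_sheep_lame_ratio()] with `ratio` and true
#'   `lame` columns.
#' @param threshold Decision threshold in [0, 1], typically the
#'   `group_separation` midpoint.
#' @return List with `verdicts` (tibble adding `predicted`, `correct`) and
#'   `accuracy_pct` (0-100).
#' @examples
#' r <- tibble::tibble(sheep_id = c("a", "b"), ratio = c(0.6, 0.4),
#'                     lame = c(TRUE, FALSE))
#' sheep_level_classify(r, 0.5)$accuracy_pct  # 100
#' @export
sheep_level_classify <- function(ratios, threshold) {
  stopifnot(is.data.frame(ratios), all(c("ratio", "lame") %in% names(ratios)))
  if (threshold < 0 || threshold > 1) stop_ovi("threshold must be in [0, 1]")
  verdicts <- ratios |>
    mutate(threshold = threshold,
           predicted = .data$ratio > threshold,
           correct = .data$predicted == .data$lame)
  list(verdicts = verdicts,
       accuracy_pct = 100 * mean(verdicts$correct))
}

#' Full sheep-level evaluation of out-of-fold predictions
#'
#' Convenience wrapper: per-sheep lame ratios, group separation
#' (delta-sigma, midpoint threshold, Mann-Whitney p) and per-sheep verdicts
#' at the midpoint threshold, from a [run_cv()] result or its predictions
#' table.
#'
#' @param x A `cv_result` or a predictions tibble with `sheep_id`, `lame`,
#'   `predicted_lame`.
#' @return List with `ratios`, `separation` (a `group_separation`),
#'   `verdicts` and `accuracy_pct`.
#' @export
sheep_level_evaluation <- function(x) {
  preds <- if (inherits(x, "cv_result")) x$predictions else x
  ratios <- per_sheep_lame_ratio(preds)
  if (!"lame" %in% names(ratios)) stop_ovi("predictions need the true `lame` label")
  sep <- sigma_difference(ratios)
  cls <- sheep_level_classify(ratios, sep$threshold)
  list(ratios = ratios, separation = sep,
       verdicts = cls$verdicts, accuracy_pct = cls$accuracy_pct)
}
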