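#' Published field-study accounting tables
#'
#' Small reference tables transcribed from the field study this package
#' models, used to check the package's accounting arithmetic against the
#' published numbers.
#'
#' `study_window_counts()` gives the number of 7 s window samples per
#' behaviour and lameness class (23 sheep-day recordings, 20 104 windows in
#' total). `study_sheep_outcomes()` gives the published sheep-level
#' outcomes: the per-activity decision threshold (percent of windows
#' classified lame above which a sheep is declared lame) and the
#' correct/total sheep counts.
#'
#' @return A tibble.
#' @examples
#' study_window_counts()
#' @export
study_window_counts <- function() {
  tibble(
    activity = rep(c("walking", "standing", "lying"), each = 2),
    lameness = rep(c("non-lame", "lame"), 3),
    n_windows = c(2974L, 3370L, 3822L, 3591L, 2271L, 4076L)
  )
}

#' @rdname study_window_counts
#' @export
study_sheep_outcomes <- function() {
  tibble(
    activity = c("walking", "standing", "lying"),
    threshold_pct = c(54.93, 50, 73.45),
    n_correct = c(16L, 12L, 11L),
    n_total = c(18L, 15L, 12L)
  )
}

#' Within-behaviour sample accounting
#'
#' Recomputes, from a per-behaviour/lameness window count table, the
#' within-behaviour percentage of each lameness class, each behaviour's
#' share of all windows, and the grand total — the bookkeeping used to
#' describe dataset composition.
#'
#' @param counts Tibble like [study_window_counts()]: `activity`,
#'   `lameness`, `n_windows`.
#' @return List with `by_class` (adds `pct_within_behaviour`),
#'   `by_activity` (`n_windows`, `pct_of_total` per behaviour) and
#'   `total_windows`.
#' @examples
#' behaviour_accounting(study_window_counts())$total_windows  # 20104
#' @export
behaviour_accounting <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("activity", "lameness", "n_windows") %in% names(counts)))
  by_class <- counts |>
    group_by(.data$activity) |>
    mutate(pct_within_behaviour = 100 * .data$n_windows / sum(.data$n_windows)) |>
    ungroup()
  total <- sum(counts$n_windows)
  by_activity <- counts |>
    group_by(.data$activity) |>
    summarise(n_windows = sum(.data$n_windows), .groups = "drop") |>
    mutate(pct_of_total = 100 * .data$n_windows / total)
  list(by_class = by_class, by_activity = by_activity, total_windows = total)
}

#' Sheep-level accuracy from correct/total counts
#'
#' @param n_correct,n_total Integer counts of correctly classified and total
#'   sheep (vectorised).
#' @return Accuracy in percent.
#' @examples
#' sheep_accuracy_pct(16, 18)  # 88.89
#' @export
sheep_accuracy_pct <- function(n_correct, n_total) {
  if (any(n_total <= 0)) stop_ovi("n_total must be positive")
  if (any(n_correct < 0 | n_correct > n_total)) {
    stop_ovi("n_correct must lie in [0, n_total]")
  }
  100 * n_correct / n_total
}
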