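#' Rank features by ReliefF relevance
#'
#' Filter-style feature ranking for the binary lameness problem. Features
#' are min-max normalised; for each evaluated instance the `k_neighbors`
#' nearest hits (same class) and nearest misses (other class) under L1
#' distance are found, and each feature's weight accumulates
#' `diff(f, x, miss) - diff(f, x, hit)` averaged over instances and
#' neighbours, where `diff` is the normalised absolute difference. With
#' `n_iterations = NULL` (default) every instance is evaluated — a
#' deterministic exhaustive variant; otherwise `n_iterations` instances are
#' sampled under `seed`. Neighbour-distance ties are broken by instance
#' index. Weights lie in [-1, 1]; a constant feature scores exactly 0.
#'
#' @param feature_table Data frame holding the feature columns plus a
#'   logical/binary label column; typically an [extract_features()] table.
#' @param label Name of the label column (default `"lame"`).
#' @param features Character vector of feature columns to rank (default: the
#'   32 canonical [feature_names()] present in the table).
#' @param k_neighbors Neighbours per class (default 10); truncated with a
#'   warning when a class is smaller.
#' @param n_iterations Number of sampled instances, or `NULL` for all.
#' @param seed Integer seed (only used when sampling).
#' @param activity Optional context label carried into the result.
#' @return A `ranked_features` object: tibble with `rank`, `feature`,
#'   `weight` (non-increasing), `activity`, plus parameters in attributes.
#' @examples
#' tab <- tibble::tibble(lame = rep(c(TRUE, FALSE), 20),
#'                       a = rep(c(1, 0), 20), b = runif(40))
#' relieff_rank(tab, features = c("a", "b"), k_neighbors = 3)
#' @export
relieff_rank <- function(feature_table, label = "lame", features = NULL,
                         k_neighbors = 10, n_iterations = NULL, seed = 1L,
                         activity = NA_character_) {
  stopifnot(is.data.frame(feature_table))
  features <- features %||% intersect(feature_names("both"), names(feature_table))
  if (length(features) < 1) stop_ovi("no feature columns found to rank")
  y <- as.logical(feature_table[[label]])
  if (anyNA(y)) stop_ovi("label column '%s' contains missing values", label)
  if (length(unique(y)) < 2) stop_ovi("label is constant; ReliefF needs both classes")
  X <- as.matrix(feature_table[, features, drop = FALSE])
  if (anyNA(X)) stop_ovi("feature table contains missing values")
  n <- nrow(X)
  if (min(table(y)) < 2) stop_ovi("need >= 2 instances per class")

  # min-max normalisation; constant features get range 1 so their diff is 0
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  Xn <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/")

  k_hit <- min(k_neighbors, min(sum(y), sum(!y)) - 1L)
  k_miss <- min(k_neighbors, min(sum(y), sum(!y)))
  if (k_hit < k_neighbors || k_miss < k_neighbors) {
    warn(sprintf("class too small for k = %d neighbours; truncated to %d hits / %d misses",
                 k_neighbors, k_hit, k_miss))
  }
  if (k_hit < 1) stop_ovi("smallest class has < 2 instances; cannot find hits")

  if (is.null(n_iterations) || n_iterations >= n) {
    eval_idx <- seq_len(n)
  } else {
    set.seed(seed)
    eval_idx <- sort(sample.int(n, n_iterations))
  }
  m <- length(eval_idx)

  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  w <- numeric(length(features))
  for (i in eval_idx) {
    d <- D[i, ]
    same <- which(y == y[i]); same <- same[same != i]
    other <- which(y != y[i])
    hits <- same[order(d[same], same)][seq_len(k_hit)]
    misses <- other[order(d[other], other)][seq_len(k_miss)]
    dh <- abs(Xn[hits, , drop = FALSE] -
                matrix(Xn[i, ], k_hit, ncol(Xn), byrow = TRUE))
    dm <- abs(Xn[misses, , drop = FALSE] -
                matrix(Xn[i, ], k_miss, ncol(Xn), byrow = TRUE))
    w <- w + colSums(dm) / (m * k_miss) - colSums(dh) / (m * k_hit)
  }
  w <- pmin(1, pmax(-1, unname(w)))   # clip float overshoot at the bounds
  ord <- order(-w, features)
  out <- tibble(rank = seq_along(features), feature = features[ord],
                weight = w[ord], activity = activity)
  structure(out, class = c("ranked_features", class(out)),
            params = list(k_neighbors = k_neighbors, n_iterations = n_iterations,
                          seed = seed, n_instances = n))
}

#' Top-ranked feature names
#'
#' @param ranking A `ranked_features` object from [relieff_rank()].
#' @param k How many top features (1 to the number ranked).
#' @return Character vector of the first `k` feature names in rank order.
#' @export
top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "ranked_features"))
  if (k < 1 || k > nrow(ranking)) {
    stop_ovi("k must be in [1, %d] (got %s)", nrow(ranking), k)
  }
  ranking$feature[seq_len(k)]
}

#' Rank features per activity
#'
#' Runs [relieff_rank()] separately on each activity subset of a feature
#' table, matching the per-behaviour reporting of the study design.
#'
#' @inheritParams relieff_rank
#' @return Tibble of stacked rankings with an `activity` column.
#' @export
relieff_rank_by_activity <- function(feature_table, label = "lame",
                                     k_neighbors = 10, n_iterations = NULL,
                                     seed = 1L) {
  purrr::map_dfr(sort(unique(feature_table$activity)), function(a) {
    relieff_rank(feature_table[feature_table$activity == a, , drop = FALSE],
                 label = label, k_neighbors = k_neighbors,
                 n_iterations = n_iterations, seed = seed, activity = a)
  })
}
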