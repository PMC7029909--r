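# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (explicit O(n^2) DFT sums, full enumeration)
# so implementation and check stay decoupled.

# brute-force DFT: X_k = sum_n x_n exp(-2*pi*i*k*n/N), explicit sum per bin
oracle_dft <- function(x) {
  n <- length(x)
  idx <- 0:(n - 1)
  vapply(0:floor(n / 2), function(k) {
    sum(x * exp(-2i * pi * k * idx / n))
  }, complex(1))
}

# all spectral quantities from the brute-force DFT, mirroring the stated
# conventions (one-sided, interior bins doubled, DC excluded from rhythm
# features, ties toward lower frequency)
oracle_spectral <- function(x, fs) {
  n <- length(x)
  X <- oracle_dft(x)
  nb <- length(X)
  amp <- Mod(X)
  p2 <- amp^2 / n^2
  one <- p2
  last_interior <- if (n %% 2 == 0) nb - 1 else nb
  if (last_interior >= 2) one[2:last_interior] <- 2 * one[2:last_interior]
  freqs <- (0:(nb - 1)) * fs / n
  total <- sum(one)
  se <- if (total == 0) 0 else {
    p <- one / total
    p <- p[p > 0]
    -sum(p * log(p))
  }
  pw <- one[-1]
  fr <- freqs[-1]
  ord <- order(-pw, fr)
  dom <- fr[ord[1:3]]
  spa <- 2 * sum(p2[-1])
  k <- 1:(nb - 1)
  even <- sum(amp[-1][k %% 2 == 0])
  odd <- sum(amp[-1][k %% 2 == 1])
  hr <- if (odd == 0) 0 else even / odd
  list(se = se, dominant = dom[1], second = dom[2], third = dom[3],
       spa = spa, hr = hr)
}

# expected window count for a fully annotated differenced stream of length n
oracle_window_count <- function(n, wlen = 112, step = 56) {
  if (n < wlen) 0L else as.integer(floor((n - wlen) / step) + 1L)
}

# metrics recomputed by enumerating prediction/label pairs
oracle_metrics <- function(tp, tn, fp, fn) {
  pred <- c(rep(TRUE, tp), rep(FALSE, fn), rep(TRUE, fp), rep(FALSE, tn))
  truth <- c(rep(TRUE, tp + fn), rep(FALSE, fp + tn))
  safe <- function(num, den) if (den == 0) 0 else num / den
  acc <- mean(pred == truth)
  prec <- safe(sum(pred & truth), sum(pred))
  rec <- safe(sum(pred & truth), sum(truth))
  list(accuracy = acc, precision = prec, recall = rec,
       f_score = safe(2 * prec * rec, prec + rec),
       specificity = safe(sum(!pred & !truth), sum(!truth)))
}

# exact two-sided Mann-Whitney p for tiny samples by enumerating every
# assignment of ranks to group 1
oracle_mw_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vals <- c(x, y)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(ix) {
    a <- vals[ix]; b <- vals[-ix]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  })
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# naive ReliefF (exhaustive, binary) written as plain loops
oracle_relieff <- function(X, y, k) {
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  Xn <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
  w <- numeric(p)
  for (i in seq_len(n)) {
    d <- sapply(seq_len(n), function(j) sum(abs(Xn[i, ] - Xn[j, ])))
    hits <- setdiff(which(y == y[i]), i)
    misses <- which(y != y[i])
    hits <- hits[order(d[hits], hits)][1:k]
    misses <- misses[order(d[misses], misses)][1:k]
    for (f in seq_len(p)) {
      w[f] <- w[f] + sum(abs(Xn[misses, f] - Xn[i, f])) / (n * k) -
        sum(abs(Xn[hits, f] - Xn[i, f])) / (n * k)
    }
  }
  w
}
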