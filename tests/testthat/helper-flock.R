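# Shared fixtures built once per test run. The large flocks (24 sheep,
# ~300 windows each) back the heavier end-to-end checks; everything is a
# deterministic function of the seeds fixed here.

.fixtures <- new.env(parent = emptyenv())

# 24-sheep flock at the requested effect size, ~310 windows per sheep
big_flock_features <- function(effect_size) {
  key <- paste0("big_", effect_size)
  if (is.null(.fixtures[[key]])) {
    cfg <- sim_config(recording_duration = 1100, n_lame = 12, n_nonlame = 12,
                      rng_seed = 101L)
    prof <- sheep_profiles(cfg, effect_size = effect_size)
    .fixtures[[key]] <- extract_features(preprocess_flock(simulate_flock(cfg, prof)))
  }
  .fixtures[[key]]
}

# small flock for structural tests
small_flock <- function(effect_size = 1, seed = 5L, duration = 150,
                        n_lame = 2, n_nonlame = 2) {
  cfg <- sim_config(recording_duration = duration, n_lame = n_lame,
                    n_nonlame = n_nonlame, rng_seed = seed)
  simulate_flock(cfg, sheep_profiles(cfg, effect_size = effect_size))
}

# gaussian feature table with a given number of informative columns
synthetic_table <- function(n, informative = 0, noise_cols = 4, delta = 2,
                            seed = 1L) {
  set.seed(seed)
  lame <- rep(c(TRUE, FALSE), length.out = n)
  cols <- list()
  nm <- feature_names("both")
  for (j in seq_len(informative)) {
    cols[[nm[j]]] <- rnorm(n, mean = ifelse(lame, delta, 0))
  }
  for (j in seq_len(noise_cols)) {
    cols[[nm[informative + j]]] <- rnorm(n)
  }
  tibble::tibble(sheep_id = sprintf("s%02d", rep(1:8, length.out = n)),
                 window_index = seq_len(n), activity = "standing",
                 lame = lame, !!!cols)
}
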