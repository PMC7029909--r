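# ovisense

Lameness is the dominant health and welfare problem in sheep production, and
it is still detected by eye — impractical on large flocks, and sheep mask
lameness around humans. `ovisense` implements a two-phase pipeline for
detecting lameness from ear-tag inertial sensors (tri-axial accelerometer in
g, tri-axial gyroscope in °/s, sampled at 16 Hz): phase 1 classifies the
current activity (walking, standing, lying), phase 2 applies an
activity-specific lameness classifier. The package is aimed at researchers in
precision livestock sensing who want a tested, fully reproducible desk-scale
instantiation of that analysis — including a synthetic flock generator, so
every stage runs without any field data.

## What it computes

Signal representation. For each modality the tri-axial signal is collapsed to
its Euclidean norm, e.g. Ā = √(Aₓ² + A_y² + A_z²), and the static component
(gravity, ear-tag orientation) is removed exactly by first differencing,
d[i] = m[i+1] − m[i]. The differenced magnitudes are segmented into 7 s
windows (112 samples at 16 Hz) with 50 % overlap; windows whose raw sensor
magnitude is identically zero are discarded as recording faults.

Features. Each window yields 16 characteristics per modality (32 in total):
eight order/moment statistics (mean, SD, min, max, median, skewness,
kurtosis, interquartile range), zero crossings of the mean-subtracted window,
signal area SA = Σ|Mag|/f_s, and from the un-tapered DFT periodogram the
spectral entropy SE = −Σ PSD_norm(f)·log PSD_norm(f), the dominant and the
2nd/3rd-ranked frequencies, the spectral area SpA = 2 Σₙ≥₁ S(fₙ)·Δf and the
harmonic ratio HR = Σ even-bin amplitudes / Σ odd-bin amplitudes.

Modelling. Features are ranked per activity with ReliefF (exhaustive,
k = 10 neighbours, L1 distance on min–max-normalised features). Five
classifiers are benched under lameness-stratified 10-fold cross-validation:
random forest (250 trees), RBF SVM, a single-hidden-layer ReLU network
(100 units, learning rate 1e-4), AdaBoost (100 depth-1 stumps) and KNN
(K = 5). A grouped-by-sheep CV mode is available as the leakage-free
alternative to the study design's lameness-only stratification.

Sheep-level evaluation. From out-of-fold predictions, each sheep's
lame-window ratio is compared between groups with the σ-difference
Δσ = (μ_lame − σ_lame) − (μ_nonlame + σ_nonlame) (positive ⇔ the 1-SD
intervals separate), a two-sided Mann–Whitney U test, and per-sheep verdicts
at the midpoint threshold (μ_lame + μ_nonlame)/2.

## Worked example

```r
library(ovisense)

cfg  <- sim_config(recording_duration = 700, n_lame = 6, n_nonlame = 6, rng_seed = 11)
prof <- sheep_profiles(cfg, effect_size = 2)      # lame gait shifted by 0.5 Hz, etc.
feats <- simulate_flock(cfg, prof) |>
  preprocess_flock() |>
  extract_features(f_s = 16)

fw <- dplyr::filter(feats, activity == "walking")
rk <- relieff_rank(fw)
head(tidy(rk), 3)
#> # A tibble: 3 × 4
#>   activity  rank feature                  weight
#>   <chr>    <int> <chr>                     <dbl>
#> 1 <NA>         1 gyro_dominant_frequency   0.855
#> 2 <NA>         2 accel_dominant_frequency  0.655
#> 3 <NA>         3 accel_harmonic_freq2      0.437

cv <- run_cv(fw, classifier_spec("rf", seed = 7), ranking = rk, n_features = 10)
glance(cv)$overall_accuracy
#> [1] 1

ev <- sheep_level_evaluation(cv)
ev$separation
#> <group_separation> delta_sigma 1.0000, threshold 0.5000
#>   (lame 1.000+/-0.000, non-lame 0.000+/-0.000), U 36.0, p 0.001262
```

At effect size 2 the injected walking perturbation (stride frequency shifted
by 0.5 Hz plus a phase-jittered head nod) is essentially perfectly separable:
the ReliefF ranking is led by the dominant-frequency features of both
modalities, the
10-fold CV accuracy is 1.0, every lame sheep has lame-window ratio 1 and
every sound sheep 0, so Δσ = 1 and the Mann–Whitney test is significant.
Standing and lying, where lameness only raises the rate of weight-shift /
restlessness events, are harder (≈ 0.85–0.87 window-level accuracy at the
same effect size). At `effect_size = 0` lame and non-lame recordings are
generated identically and everything collapses to chance.

`autoplot()` methods are provided for rankings, feature-count sweeps
(`feature_sweep()`) and sheep-level separations; `run_pipeline()` executes
the whole chain (simulate → preprocess → extract → rank → CV → sheep level)
with one seed and writes stage CSVs plus a digest manifest.

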