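# symbolichar

Symbolic representation and classification of triaxial inertial-sensor time
series, for human activity recognition (HAR) on resource-constrained devices.

Shallow HAR pipelines usually turn accelerometer windows into dozens of
hand-crafted time- and frequency-domain features. Symbolic pipelines instead
discretize each window into a short **word** over a small alphabet and
classify activities from word-frequency histograms — a representation that is
cheap to compute, cheap to store (letters pack into a couple of bits), and
naturally noise-reducing. `symbolichar` implements the two standard
discretizers and the four classifiers built on them, the fusion strategies
that let one-dimensional symbolic methods handle x/y/z signals, a synthetic
activity-signal generator, and a cross-validation harness that also accounts
for representation size.

**Discretizers**

- **SAX** — z-normalize a window (`x' = (x - mu) / sigma`), reduce it to `l`
  frame means with piecewise aggregate approximation (PAA), and map each mean
  to a letter through equal-probability Gaussian breakpoints
  (`beta_i = Phi^-1(i/c)`). Includes numerosity reduction and the
  lower-bounding word distance
  `MINDIST = sqrt(n/l) * sqrt(sum_i cell(a_i, b_i)^2) <= d_Euclid`.
- **SFA** — quantize the leading Fourier coefficients of each window, one
  learned breakpoint row per real/imaginary coefficient column (Multiple
  Coefficient Binning, equi-depth by default), with an incremental
  sliding-window transform (MFT) for dense extraction. The supervised variant
  (**SFA-W**, used by WEASEL) selects coefficient columns by one-way ANOVA F
  and places breakpoints by recursive information-gain binning.

**Classifiers**

- **SAX-VSM** / **BOSS-VS** — per-class bags of words weighted by
  `tf*idf` (`tf = log10(1 + f)`, `idf = log10(T / d)`), cosine-similarity
  classification.
- **BOSS** — 1-NN on the asymmetric histogram distance
  `dist(h1, h2) = sum_{w: h1(w) > 0} (h1(w) - h2(w))^2`.
- **WEASEL** — unigram + bigram word counts across windows, chi-squared
  feature screening, multinomial logistic regression.

**Axis fusion** — `stack` (per-axis words pooled into one axis-tagged
histogram), `magnitude` (`sqrt(x^2 + y^2 + z^2)`), `pca` (projection on the
leading covariance eigenvector, fitted on training folds only).

## Worked example

```r
library(symbolichar)

# 4-class synthetic accelerometer streams: 10 users x 4 bouts x 4 activities
frame <- generate_synthetic_har(synthetic_spec())
instances <- collect_instances(frame)      # 160 bouts, 250 samples each

cv <- cross_validate(instances, har_pipeline("bossvs", "stack"),
                     k = 10, seed = 42)
cv
#> 10-fold CV (instance level): bossvs / stack fusion
#>   mean accuracy: 99.4% (fold range 93.8% - 100.0%)

glance(cv)
#> # A tibble: 1 x 7
#>   classifier fusion     k unit     mean_accuracy sd_accuracy     n
#>   <chr>      <chr>  <dbl> <chr>            <dbl>       <dbl> <int>
#> 1 bossvs     stack     10 instance         0.994      0.0198   160
```

The mean accuracy is the average held-out accuracy over ten stratified folds;
every data-dependent component (MCB breakpoints, idf table, PCA rotation)
is refitted inside each training fold. `autoplot(cv)` draws the confusion
matrix; `autoplot(frame)` shows the raw signals per activity.

Lower-level entry points mirror the method stack: `sax_transform()`,
`fit_mcb()` / `sfa_transform()`, `fit_sfa_supervised()`, `build_class_bags()`
/ `tfidf_matrix()` / `classify_vsm()`, `boss_distance()` /
`classify_boss_1nn()`, `weasel_featurize()` / `train_linear_classifier()`,
`fuse_magnitude()` / `fit_pca_fusion()`, `time_features()` /
`freq_features()`, `pack_words()` / `profile_cost()`.

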