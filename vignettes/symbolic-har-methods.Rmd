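---
title: "Symbolic representation methods for activity recognition: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symbolic representation methods for activity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbolichar)
```

## The problem and the representation

Human activity recognition from body-worn accelerometers classifies short
stretches of a triaxial signal into activities (walking, running, sitting,
standing, ...). The conventional shallow pipeline extracts dozens of numeric
features per window; the symbolic alternative implemented here discretizes
each window into a short *word* over a small alphabet and classifies from
word-frequency histograms. Words compress aggressively (a 4-letter alphabet
needs 2 bits per letter), act as a noise filter (both PAA averaging and
truncated Fourier expansion are low-pass operations), and admit fast
bag-of-words classifiers.

Two discretizers are provided.

**SAX** z-normalizes the window to zero mean and unit *population* standard
deviation, averages it into `word_length` PAA frames, and assigns each frame
mean a letter via breakpoints that cut the standard normal density into
`alphabet_size` equal-probability regions. Under z-normalization the frame
means are approximately standard normal, so letters are approximately
uniform — each letter carries maximal information. The word distance
`MINDIST` (frame-wise breakpoint gaps, scaled by `sqrt(n/l)`) provably never
exceeds the Euclidean distance of the underlying z-normalized windows; the
test suite exercises this on 1000 random pairs.

**SFA** represents the window by its leading Fourier coefficients and learns
one breakpoint row *per* real/imaginary coefficient column from training
data (MCB). Because bins adapt to each coefficient's empirical distribution,
SFA tracks the signal's spectral shape more faithfully than PAA at equal
word length. The sliding-window transform is computed incrementally (MFT):
shifting a window by one sample updates each coefficient with one complex
multiply-add, and the tests require agreement with a direct transform to
1e-9. The supervised variant SFA-W (used by WEASEL) replaces both phases:
a one-way ANOVA F statistic picks the most class-discriminative coefficient
columns among all available ones, and breakpoints come from recursive
information-gain binning on the class labels.

## Classifiers

* **SAX-VSM / BOSS-VS** pool all training words of a class into one bag,
  weight words by `tf*idf` with `tf = log10(1 + count)` (exactly 0 for a
  zero count) and `idf = log10(T / d)` over the `T` classes, and classify a
  query histogram by cosine similarity against the class weight vectors.
  Words shared by all classes get idf 0 and drop out; query words unseen in
  training contribute nothing (their idf is undefined, so the weight is 0).
* **BOSS** keeps one histogram per training instance and classifies by 1-NN
  under the asymmetric distance `sum over words in the query histogram of
  squared count differences`. Restricting the sum to the query's words makes
  the comparison robust to vocabulary the training series happens to add.
* **WEASEL** builds unigram and bigram count features (bigrams pair
  consecutive *non-overlapping* words: `w1w2`, `w3w4`, ...), tags every
  feature with its window size and axis, screens features by a Pearson
  chi-squared statistic against the class labels, and fits a multinomial
  logistic regression (ridge-regularized, single fixed lambda) on the kept
  features.

Chi-squared screening *keeps* high-statistic features: the statistic
measures how far a word's class-conditional counts sit from the pooled
expectation, so large values mark exactly the class-discriminative words the
screening exists to retain. The opposite direction (discarding significant
features) is available behind the `keep` argument for completeness.

## Handling three axes with one-dimensional methods

`stack` windows each axis separately with a shared window size, tags each
word with its axis, and pools the three tagged word streams into one
histogram per instance — no classifier changes, and axis tags prevent
cross-axis collisions. `magnitude` collapses the axes to the rotation-
invariant Euclidean norm before discretization; orientation information is
deliberately lost, so static postures whose gravity vectors share a norm
become indistinguishable (see limitations). `pca` projects onto the leading
eigenvector of the 3x3 covariance of the *training* samples; the projection
is refit inside every cross-validation training fold so test data can never
influence it, and the largest-magnitude loading is forced nonnegative to
make the sign deterministic.

## Tunable parameters

| Parameter | Default | Rationale |
|---|---|---|
| window length | 1 s of samples (`fs` samples) | the standard symbolic-pipeline window for 20-50 Hz activity data; one stride/sway cycle fits in a window |
| word length `l` | 8 letters | longer words track the window more closely; 8 is the upper end of common SAX/SFA settings |
| alphabet size `c` | 4 letters | the usual SAX/SFA recommendation; 2 bits per letter |
| extraction stride | 1 sample (dense) | the bag-of-patterns convention; numerosity reduction then collapses repeats. Sparse extraction is available via `overlap` |
| SFA `normalize` | `TRUE` | z-normalizes windows and drops the DC coefficient, giving scale-invariant words |
| MCB variant | `equi_depth` | breakpoints at the `i*N/c`-th order statistics per column; `sorted_prefix` (first `c-1` sorted values) is kept as a fidelity variant but concentrates mass in the top bin |
| chi-squared threshold | 2 | mild screening; the logistic regression's ridge penalty does the fine-grained shrinkage |
| ridge lambda | 1e-3 | small enough for separable training sets to be fit exactly, large enough to keep the solution unique |
| baseline windows | 5 s, 50% overlap | feature-based baselines conventionally use longer windows than symbolic pipelines |

## Numerical choices and degenerate inputs

* Indexes are 0-based and windows half-open `[start, start + w)`.
* Bins are half-open `[beta_{i-1}, beta_i)`: a value exactly at a breakpoint
  takes the higher letter. This fixes the constant-window case: a flat
  window z-normalizes to zeros, and zero falls in the bin just above the
  median breakpoint (`"cccc..."` for `c = 4`).
* Windows with population sd below `sd_floor = 1e-8` map to the all-zero
  vector rather than amplifying numerical noise.
* PAA with a word length that does not divide the window uses fractional
  frame boundaries with proportional sample weights (exact block means when
  it does divide; verified against an upsampling oracle).
* MCB breakpoint rows are forced strictly increasing by a stable nudge of
  `1e-9 * scale` applied to duplicates; an all-constant training column
  still yields `c` distinct bins because the outer bins extend to infinity.
* Information-gain binning: each split scans all midpoints between adjacent
  distinct values; recursion continues on the partition with the largest
  label entropy. Single-class columns, zero-gain columns and columns with
  fewer distinct values than bins fall back to equi-depth placement on the
  distinct values.
* Ties: 1-NN and cosine argmax ties go to the earliest training
  instance/class in order, with a logged warning; window-label majority ties
  go to the earliest sample's label.
* Stratified folds balance both within class and globally (class remainders
  are assigned to the currently least-loaded folds), so 100 instances in 10
  folds give test sets of exactly 10.
* Fourier convention: unnormalized forward transform (`DC = window sum`),
  coefficients interleaved `(Re, Im)` starting after DC when normalized.
* `tf`/`idf` logarithms are base 10 (configurable); the zero branch of `tf`
  is exact, not a limit.
* Byte accounting is implementation-independent: raw data costs
  `samples x 3 axes x 8` bytes; a stored word costs
  `ceil(l * log2(c) / 8)` packed letter bytes plus a 4-byte start index.
  For `c = 4` the letter code is the reflected 2-bit code `a=00, b=10,
  c=11, d=01`, and packing is exactly invertible.

## The synthetic generator: what it emulates, and what it does not

`synthetic_spec()` describes a harmonic-plus-noise model: per class, a
gravity offset vector plus one sinusoid (per-bout frequency drawn around a
base cadence, random phase per bout and axis, fixed per-axis amplitude
scaling) plus white Gaussian sensor noise of 0.02 g (typical MEMS
accelerometer noise). Defaults: 50 Hz sampling, 5 s bouts, 10 users, 4
bouts per user per class, four classes — walking 2 Hz at 0.5 g, running
3 Hz at 1.0 g, sitting as gravity along -y with a faint 0.3 Hz
respiration/trunk micro-motion (0.06 g), standing as gravity along +z with
a 1 Hz postural sway (0.15 g). The cadence spread (`freq_sd`) models
step-to-step variability and keeps a bout's windows from being phase-locked
copies of one another.

Two modeling points deserve emphasis. First, per-window z-normalization —
built into SAX and into normalized SFA — erases gravity orientation and
scale, so *purely static* postures would be information-theoretically
indistinguishable to every symbolic pipeline regardless of parameters. Real
recordings are never that degenerate: seated and standing bodies carry
low-frequency physiological texture (sway, respiration), and it is this
texture that the symbolic methods actually exploit. The generator therefore
gives both static postures a small oscillatory component rather than pure
noise. Second, bag-of-patterns matching requires words to repeat: a class
whose windows are white noise produces essentially unrepeatable words and
degenerates BOSS 1-NN into distance ties. Passing tests on this generator
demonstrate correct mechanics and sensible statistical behavior at desk
scale; they do not certify accuracy on real devices, real inter-subject
variability, device orientation drift, or non-stationary activity
transitions, none of which are modeled.

The seed is split per (user, class, bout), so regenerating a subset of the
data is stable.

## Evaluation harness

`cross_validate()` performs stratified k-fold assignment at the instance
(bout) or user level and refits *every* data-dependent component inside
each training fold: MCB breakpoints, ANOVA selection and information-gain
bins, the idf table, the chi-squared mask, the PCA rotation, and the linear
model. Reports are bit-reproducible given the seed. A label-permutation
null run is the standard check that the harness cannot leak labels: its
accuracy must sit at chance within binomial error. Stage timings are
reported through `profile_cost()` but never asserted — they are
hardware-bound. The acceptance script (`scripts/acceptance.R`) re-runs the
full grid of three classifiers by three fusion strategies at the default
problem size (160 instances, 40 000 raw samples), which keeps a complete
run within minutes on one core.

## Known limitations

* Magnitude fusion cannot separate static postures whose gravity vectors
  share a norm; the default generator keeps both at 1 g deliberately, and a
  `distinct_gravity` variant (sitting at 0.6 g) exists to study the fusion's
  behavior when the norms differ.
* WEASEL is the heaviest pipeline (supervised MCB over all coefficients,
  bigram feature space, logistic fit) and is the least suited to the tiny
  per-class training sets used here; its accuracy is not a headline claim.
* The `sorted_prefix` MCB variant reproduces a narrower textual description
  of breakpoint selection and is not recommended: its bins are not
  equi-probable.
* Baseline shallow learners are a thin fit/predict contract over standard
  implementations; the package ships the Table-style time/frequency feature
  extractors, not re-implementations of the learners.
* Real-data readers support the clean header dialect and the raw
  WISDM-style dialect of delimited accelerometer logs; irregularly sampled
  streams are rejected rather than resampled.
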