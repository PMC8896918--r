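---
title: "Wavelet-domain seizure detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-domain seizure detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegseizer)
```

## The problem and the model

Epileptic (ictal) EEG differs from background activity chiefly in its
low-frequency, high-amplitude rhythmic spike-wave discharges. `eegseizer`
exploits this with a three-stage pipeline:

1. **Multiresolution decomposition.** Each segment is passed through a
   5-level discrete wavelet transform with the Daubechies-4 filter pair.
   Each level splits its input through a low-pass/high-pass
   quadrature-mirror pair and downsamples by two, so a 4096-sample
   segment yields detail subbands D1 (2048 coefficients) through D5 (128)
   plus the approximation A5 (128). The nominal band of Dj is
   `(fs/2^(j+1), fs/2^j)` Hz; at 173.61 Hz the informative bands for
   seizure activity are D3–D5 and A5 (≈ 0–21.7 Hz), which is the default
   subband selection.
2. **Feature extraction.** Seven statistics per subband: mean absolute
   value (MAV), maximum, minimum, sample SD, average power, Shannon
   entropy and approximate entropy — 28 features per segment for the
   default four subbands.
3. **Cross-validated classification.** A grid of two- and three-class
   problems (the standard 17 Bonn-set contrasts, `build_cases()`) is
   evaluated per (subband, feature, classifier) cell with stratified
   10-fold cross-validation for four classifiers, and summarised by
   accuracy, sensitivity, specificity, PPV, NPV and MCC.

## Numerical choices in the wavelet stage

**Boundary handling is periodization.** Among the common extension modes
only circular extension keeps the decimated filter bank orthonormal on
finite signals, which buys three properties the tests rely on: coefficient
counts halve *exactly* at every level; reconstruction is exact to
round-off (relative L2 error below 1e−8 is asserted; observed ≈ 1e−16);
and energy is conserved (Parseval), so subband average power is a true
energy partition. The cost is wrap-around leakage at the segment edges,
negligible for 4096-sample segments. Periodization requires the length to
be divisible by `2^levels`; `dwt_decompose()` reports the maximum feasible
depth otherwise.

**Signals are used raw.** No detrending, filtering or amplitude
normalization precedes the transform. Features that should be
scale-invariant (both entropies) are made so by their own normalization;
amplitude-carrying features (MAV, extrema, SD, power) are the
discriminative signal and must not be normalized away.

**db4 only.** The filter pair is hard-coded at double precision and the
single implemented level is pinned against an explicit
filter-matrix oracle at 1e−10 in the tests; other families would dilute
the surface without adding tested behaviour.

## Feature definitions and their parameters

* **MAV** uses the absolute value, `mean(|x|)` — it is the mean
  *absolute* value by name and standard usage.
* **SD** uses the unbiased `N−1` denominator (hence requires `N ≥ 2`).
* **Shannon entropy** needs a distribution estimate. The default is the
  normalized coefficient-energy distribution `p_i = x_i²/Σx_j²` — the
  usual "wavelet entropy", parameter-free and scale-invariant. A
  histogram estimator (`estimator = "histogram"`, `n_bins` equal-width
  bins, default 16) is provided for amplitude-domain entropy. An all-zero
  subband has no energy to distribute and returns 0. Units are bits.
* **Approximate entropy** follows Pincus: `Φ^m(r) − Φ^{m+1}(r)` with
  natural-log Φ, Chebyshev template distance and self-matches included
  (guaranteeing `ApEn ≥ 0` and a defined value for every input).
  Defaults `m = 2` and `r = 0.2 ×` the SD of the subband being measured —
  the field-standard setting for short biomedical series. The tolerance
  scales with each subband's own SD, so ApEn is comparable across
  subbands of very different energies. A constant series returns 0 by the
  regularity limit.

Column order in the feature table is fixed (subband-major; MAV, MAXC,
MINC, STD, AVP, SHEN, APEN) so feature matrices are byte-reproducible.

## Evaluation design

**Folds are stratified** (class proportions preserved to within one
sample per fold) with assignment a deterministic function of the CV seed;
pooled cases such as ABCD-E are left imbalanced (400 vs 100) — no
resampling — so prevalence-sensitive metrics (PPV, NPV) reflect the
actual class mix.

**Metrics are averaged per fold**, i.e. computed on each test fold and
then averaged over the 10 folds; a pooled-confusion computation is
available via `run_case(..., pooled = TRUE)`. Any 0/0 ratio within a fold
(e.g. NPV when a small fold has no negative predictions) is `NA` and is
dropped from that metric's mean; an MCC with zero denominator is defined
as 0. For the three-class case, metrics are one-vs-rest with the seizure
group (listed last) as positive — the clinically meaningful contrast —
plus overall accuracy from correctly-classified/total counts.

**Classifier defaults** where a choice had to be made: SVM with a linear
kernel and cost 1 (the separating-hyperplane model the method assumes;
delegated to `e1071::svm`); Gaussian naive Bayes (`e1071::naiveBayes`,
continuous features); decision tree with the Gini criterion and no depth
limit (`rpart`); kNN with `k = 3` and Euclidean distance, evaluated
directly so that ties break deterministically — majority vote, then
nearest-neighbour distance, then lowest class index. All adapters are
seeded and verified to return identical predictions on repeated calls.
Single-feature evaluation is the grid default because the benchmark
tables report per-feature results; `subband = "all", feature = "all"`
trains on the full 28-column matrix.

## What the synthetic generator emulates — and what it does not

`synth_spec()` produces two (optionally three) classes:

* **Background ("H")**: a sinusoid with per-segment random frequency in
  `background_band` (default 8–13 Hz, the alpha rhythm of relaxed,
  eyes-closed adults) and amplitude 50 µV, plus 1/f-shaped Gaussian noise
  (SD 10 µV) mimicking the broadband EEG spectrum.
* **Seizure ("S")**: the same background plus a periodic biphasic
  spike-wave complex — sharp transient followed by a slow half-sine —
  repeating at a frequency drawn from `seizure_freq_band` (default
  2.5–5 Hz, the classic spike-wave discharge range, inside the D5 band at
  the Bonn sampling rate) with amplitude 300 µV (6 × background).
* **Interictal ("I")**, optional third class: background plus sporadic
  isolated spikes (Poisson events at `spike_rate`/s, default 1) of
  intermediate amplitude.

Defaults are 100 segments per class of 4096 samples at 173.61 Hz,
mirroring the Bonn benchmark's geometry. Every segment's pseudo-random
stream is keyed by `(seed, class, index)`, so any single segment is
bit-reproducible in isolation.

This generator is deliberately *not* physiological: no neural-mass
dynamics, no fitted 1/f exponents, no artifacts, no non-stationarity
within a segment, and a class separation (6 × amplitude ratio in a known
band) far cleaner than real ictal/interictal EEG. Consequently the
end-to-end benchmark — all four classifiers reaching ≥ 95% accuracy on
D5-MAV with the permutation control at chance — demonstrates that the
pipeline is *correct and leak-free*, not that it attains any particular
accuracy on clinical recordings; published Bonn-data accuracies
additionally depend on unstated choices (entropy estimator, ApEn
parameters, SVM kernel) that this package simply makes explicit.

## Degenerate inputs and tie-breaks

Empty coefficient arrays, series too short for the requested ApEn run
length, folds requested beyond the class size, missing classes in
training data, and non-finite features are all hard errors naming the
offending segment or class rather than silent NA propagation. Best-cell
summaries (`best_results()`) break accuracy ties by grid order, which is
itself fixed, so summaries are deterministic.

## Problem sizes used by the tests

The unit suite runs on short segments (128–1024 samples, ≤ 30 segments
per class), chosen so the full suite completes in well under a minute
while still exercising 5-level decompositions and 10-fold CV. The
end-to-end benchmark and the acceptance script use the full default
geometry (100 + 100 segments × 4096 samples). ApEn is O(N²) in the
subband length; at the default subband selection the largest input is the
512-coefficient D3 band, far below the scale where that matters.

## Known limitations

* Single-channel analysis only; the multichannel readers flatten
  recordings to independent per-channel signals (no montage logic).
* Periodization's edge wrap-around makes the first/last few coefficients
  of each subband slightly mixture-of-ends; irrelevant at 4096 samples
  but worth knowing for very short segments.
* The EDF reader covers plain EDF with a common record duration; EDF+D
  (discontinuous) files and annotations are out of scope.
* Published benchmark-table values are not test oracles here: they are
  not reproducible without the original data and carry internal
  inconsistencies; the package's tests pin analytic values and
  brute-force oracles instead.
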