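---
title: "Multiscale HRV analysis with temporal pyramid pooling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale HRV analysis with temporal pyramid pooling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvpyramid)
```

## The problem and the model

Blood pressure regulation is under autonomic control, and heart rate
variability (HRV) — the beat-to-beat fluctuation of RR intervals — indexes
the balance between sympathetic and vagal drive. In hypertensive patients
HRV is depressed, and the depression deepens with disease severity.
`hrvpyramid` grades overnight recordings into *mild*, *moderate* and
*severe* classes from HRV alone, using a fine-grained multiscale analysis
rather than a single whole-night summary.

The pipeline is:

1. **Preprocess.** The raw single-lead ECG is denoised by wavelet
   shrinkage, R peaks are detected with a fixed sliding window and an
   adaptive threshold, RR intervals are derived from peak spacing, and an
   artifact rule corrects physiologically implausible intervals. Analyses
   can equally start from pre-extracted RR text files.
2. **Multiscale segmentation.** The 8-hour overnight series is cut into
   seven nested levels — windows of 480, 240, 120, 60, 30, 20 and
   5 minutes — giving 1 + 2 + 4 + 8 + 16 + 24 + 96 = 151 segments.
3. **Feature extraction.** Every segment is summarised by 18 HRV features:
   nine time-domain (MEAN, VAR, MAX, MIN, SDNN, RMSSD, SDSD, PNN50, CV),
   six frequency-domain (VLF, LF, HF, VHF, TP, LF/HF) and three nonlinear
   (DFA α₁, Rényi entropy, sample entropy).
4. **Temporal pyramid pooling.** Per feature, the 151 segment values form
   a pool. The pool is reduced to a scalar by *top-k average pooling*:
   sort descending to $a_1 \ge a_2 \ge \dots \ge a_n$ and take
   $t = \frac{1}{k}\sum_{i=1}^{k} a_i$. $k = 1$ is max pooling, $k = n$
   average pooling. The depth $k$ is chosen per feature by maximising the
   information entropy $H(X_k) = -\sum_b \hat p_b \log \hat p_b$ of the
   pooled value across the cohort, estimated from a 10-bin equal-width
   histogram: maximal entropy means the pooled feature spreads subjects
   out instead of collapsing them onto a few values.
5. **Feature selection.** Each pooled feature is scored by a one-way
   ANOVA F statistic across the three severity classes (df = 2 between
   groups); features with $F > 1$ are kept.
6. **Classification.** Naïve Bayes, an RBF SVM, a single-hidden-layer
   perceptron (the "BPNN") and a random forest are evaluated under
   stratified 10-fold cross-validation; precision and recall are
   $\mathrm{precision} = \frac{TP}{TP+FP}\times 100$,
   $\mathrm{recall} = \frac{TP}{TP+FN}\times 100$ from the pooled
   out-of-fold confusion matrix, with overall precision the
   micro-average.

Pool-depth selection and feature selection are refitted **inside every
training fold**. Selecting $k$ or the feature set on the full cohort would
leak the held-out subjects' values into the model; fitting them per fold
keeps the cross-validated estimate honest. (Whether to micro- or
macro-average the overall precision was an open choice; micro-averaging is
used and labelled as such.)

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| scale levels | 480, 240, 120, 60, 30, 20, 5 min | nested divisors of 8 h; 5 min is the canonical short-term HRV window |
| min beats / segment | 10 | a sparser 5-min window is physiologically implausible and breaks spectral estimation; such segments are dropped from the pool and the realised pool length recorded |
| spectral bands | VLF 0.003–0.04, LF 0.04–0.15, HF 0.15–0.40, VHF 0.40–0.50 Hz | standard HRV bands; TP is their union 0.003–0.50 Hz |
| tachogram resampling | 4 Hz cubic spline, Welch (≤ 256-sample Hann segments, 50 % overlap) | the standard FFT route for unevenly sampled tachograms; well behaved at the 5-min scale |
| SampEn | m = 2, r = 0.2·SDNN | conventional defaults; evaluated on at most the first 2000 intervals of very long segments, where the estimator has long converged, to bound the quadratic kernel |
| DFA | boxes 4–16 (α₁) | short-range exponent; white noise ⇒ α ≈ 0.5 (the small boxes carry a known positive finite-size bias of ≈ +0.08 on white noise) |
| Rényi entropy | order 2, 10 bins | collision entropy of the interval histogram |
| entropy bins for k selection | 10 | equal-width histogram, natural log; H ranges 0 … ln 10 ≈ 2.30 |
| F threshold | 1.0, strict | features at exactly the threshold are dropped |
| RF | 100 trees, √p splits | seeded; no tuning performed |
| wavelet | Daubechies-6 MODWT | depth chosen so the approximation band is < 0.5 Hz at the record's rate (7 levels at 128 Hz, 8 at 250 Hz) |

## Numerical choices and edge cases

* **Windows are half-open `[start, end)`**, so a beat exactly on a
  boundary belongs to the right-hand window and every interval onset falls
  in exactly one segment per level. Pools are ordered coarsest level
  first, chronological within level; any fixed order works because the
  pooling function sorts, but a fixed order keeps artifacts reproducible.
* **Population variance** is used for VAR/SDNN *and* for SDSD, so the
  identity RMSSD² = SDSD² + (mean ΔRR)² holds exactly and golden test
  values are stable.
* **Candidate pool depths start at k = 1** (k = 0 would make the pooling
  mean undefined); entropy ties are broken toward the smallest k.
* **Degenerate inputs**: constant segments have zero SDNN/RMSSD/entropy
  and zero band powers; LF/HF is undefined (NA, with a warning) when HF
  is zero; zero-variance SampEn is 0 by the r = 0 matching convention; a
  flat ECG yields an empty peak list with a warning rather than an error.
* **ANOVA degeneracy**: equal group means give F = 0 even when the within
  variance is also zero; zero within-variance with unequal means reports
  an infinity sentinel with a warning.
* **Peak-detector threshold.** The adaptive threshold is 0.5 × the
  99.5th-percentile amplitude of the surrounding 10-s block. The QRS
  positive lobe occupies only a few percent of samples at normal heart
  rates, so low quantiles (e.g. the 95th) sit in the inter-beat noise
  floor and admit spurious maxima whenever an RR interval exceeds the
  sliding window; the top half-percent tracks the R amplitude itself.
* **RR correction** flags intervals outside 300–2000 ms or deviating more
  than 20 % from the 11-beat rolling median — standard Holter artifact
  rules, all configurable — and replaces them with the median of nearby
  *unflagged* intervals (so an outlier at a record edge is never replaced
  by itself). Beat times are rebuilt from the corrected intervals; the
  operation is idempotent. Records with > 20 % flagged intervals are
  rejected.
* **Wavelet denoising** zeroes the sub-0.5 Hz approximation (baseline
  wander) and soft-thresholds only the finest detail level (upper half of
  the spectrum) with the universal threshold; the 5–15 Hz QRS band passes
  untouched. The signal is reflection-padded before the circular MODWT so
  record edges are clean.

## The synthetic cohort: what it does and does not emulate

No clinical recordings ship with the package; every pipeline stage is
exercised against a seeded generator. A subject's tachogram is

$$rr(t) = \mu + A_{LF}\sin(2\pi \cdot 0.10\,t) +
  A_{HF}\sin(2\pi \cdot 0.25\,t + \varphi) + \varepsilon,$$

with $\varepsilon$ white Gaussian noise. Class targets encode the
clinical direction — HRV depressed and LF/HF elevated with severity:
mild (mean RR 900 ms, SDNN 55 ms, LF/HF 1.5), moderate (850, 40, 2.5),
severe (800, 25, 4.0). The two oscillators carry 45 % of the target
variance, split so their power ratio equals the LF/HF target; the noise
absorbs the rest, which keeps the SDNN target exactly reachable by
construction. Each subject's targets are jittered with a 12 % coefficient
of variation — without inter-subject heterogeneity every subject in a
class would be statistically identical, the cohort entropy curves would
degenerate and classification would be trivial. A configurable fraction
of beats (2 % in the study conditions) is replaced by ectopic-like
shortenings (×0.45) or block-like pauses (×2.2). ECG waveforms, when
needed, are Ricker-wavelet QRS templates of 1 mV placed at the beat
times, plus sinusoidal baseline drift and white noise.

What this deliberately does **not** model: circadian and sleep-stage
structure, respiratory frequency drift, 1/f-like long-range correlations,
beat-morphology variation, or realistic P/T waves. Passing tests
therefore demonstrate that the machinery — segmentation, features,
pooling, selection, validation — is correct and leak-free, not that the
classifier's synthetic accuracy transfers to clinical Holter data, whose
class overlap is far larger.

## Problem sizes used in the checks

The shipped tests and the acceptance script run the full study conditions
at 30 subjects per class (90 overnight records of ≈ 30,000 beats), which
the pipeline processes in a few minutes; unit tests use 60-minute records
with a shortened four-level scheme (60, 30, 20, 5 min) where only the
mechanics are under test. ECG-level round trips use 10-minute records at
128 and 250 Hz. The label-permuted control repeats the cross-validation
under 10–20 permutation seeds and should sit at the three-class chance
level of ≈ 33 %.

## Known limitations

* A univariate F per feature ("MANOVA" in the loose sense) ignores
  feature correlation; a true multivariate statistic (Wilks' Λ) is out of
  scope.
* Entropy-based k selection depends on the histogram estimator; with very
  small cohorts (< ~10 subjects) the 10-bin histogram is noisy and k
  selection close to arbitrary.
* The WFDB reader covers formats 16 and 212, single- or multi-channel
  (channel 0-indexed conventions differ between tools; here `channel` is
  1-based). EDF and annotation files are out of scope.
* With fewer than 100 intervals DFA and SampEn are undefined and the
  segment is dropped from the pools, so extreme bradycardia in a 5-min
  window shortens the realised pool.

## A minimal run

```{r pipeline, eval = FALSE}
metrics <- run_pipeline(list(
  input = list(simulate = list(n_per_class = 30, seed = 42,
                               artifact_rate = 0.02)),
  classifier = "rf", folds = 10, seed = 42,
  out_dir = "hrvpyr_out"
))
print(metrics)
```

The same flow is available from a shell through the thin wrapper
`exec/hrvpyr` (`hrvpyr simulate`, `hrvpyr run-pipeline`), and
`scripts/acceptance.R` recomputes the headline quantities from scratch
(see the README).
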