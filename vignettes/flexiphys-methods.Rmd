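---
title: "Methods: from psychophysiological signals to flexibility discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from psychophysiological signals to flexibility discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexiphys)
```

## The problem

Mental flexibility — the capacity to shift thought and behaviour as demands
change — is usually assessed with neuropsychological tests and self-report
questionnaires. A complementary view reads it off the autonomic nervous
system: heart-rate variability (HRV), breathing dynamics, facial-muscle
activity and electrodermal tone differ between people who score high versus
low on the Cognitive Flexibility Inventory (CFI). flexiphys implements the
full computational path for that comparison:

1. raw signal handling (blood volume pulse, respiration, two facial EMG
   channels, skin conductance), with rate conversion between the 2048 Hz
   acquisition rate and the 256 Hz (32 Hz for conductance) analysis rates;
2. feature extraction per subject: time-, frequency- and Poincaré-domain
   HRV from the pulse-derived inter-beat intervals, breath-by-breath
   respiration rate, EMG RMS-envelope ratios, conductance summaries;
3. group statistics: a median split of the CFI, normality screening, and
   pooled-variance independent t-tests with Cohen's d — from raw data or
   directly from published group summaries;
4. machine-learning comparison: information-gain feature ranking,
   leave-one-out cross-validated (LOOCV) kNN / SVM / random-forest /
   naive-Bayes classification, and an information-gain decision tree whose
   paths read as threshold rules.

Because the original recordings are not publicly deposited, the package
also ships generators that synthesize each signal class with known ground
truth and cohorts drawn from the published group summary statistics, so
every stage is testable end to end.

## Signal model and feature definitions

**Inter-beat intervals.** Beats are the maxima of the blood-volume-pulse
wave. Detection thresholds candidate maxima at the 5th percentile plus
0.3 of the 5th–95th percentile span, enforces a 300 ms refractory period,
and refines each peak to sub-sample precision with a parabolic fit through
the peak and its neighbours. Intervals outside 300–2000 ms are treated as
artifacts and the series re-spliced. Per-beat pulse amplitude is peak
minus preceding trough.

**Time domain.** SDNN is the sample SD (n−1) of the intervals; RMSSD the
root mean square of successive differences; NN50/pNN50 count successive
differences strictly greater than 50 ms; Max/Min HR are the extrema of
60000 over an N-beat moving average of the intervals. N is nowhere
standardized for pulse-derived series; the default is N = 5, configurable,
which smooths single-beat noise while tracking genuine rate excursions.

**Frequency domain.** The interval series, attributed to the time of each
closing beat, is interpolated to an evenly sampled tachogram (cubic
spline, 4 Hz), mean-removed, and its power spectral density estimated by
Welch's method (Hann window, 64 s segments, 50% overlap — the classical
short-recording HRV recipe; all configurable). Band powers integrate the
density over VLF < 0.04 Hz, LF 0.04–0.15 Hz and HF 0.15–0.5 Hz (the upper
HF edge here is 0.5 Hz, wider than the conventional 0.4 Hz, matching the
band definition this pipeline reproduces). The LF/HF ratio is the usual
sympathovagal balance index. "Peak frequency" is reported both as the
frequency of the in-band spectral maximum and as the density magnitude at
that maximum, since either reading occurs in practice. VLF estimates from
recordings shorter than 300 s are flagged unreliable.

**Poincaré indices.** With lagged pairs (x, y) = (IBI~k~, IBI~k+1~), SD1
measures dispersion perpendicular to the identity line and SD2 along it.
SD1 is computed as the uncentred RMS of (y − x)/√2, exactly matching the
RMSSD convention, so the classical identity SD1 = RMSSD/√2 holds to
machine precision; a mean-centred SD1 would differ from RMSSD/√2 by the
(tiny) squared mean successive difference, which is why the convention is
pinned here. SD2 is the sample SD of (x + y)/√2. The ratio is reported as
SD2/SD1 (values above 1 for typical series), with the reciprocal also
available.

**Respiration.** The trace is band-passed to 0.05–1 Hz with a zero-phase
Butterworth filter, breath maxima are detected with a 1 s refractory
period, each maximum-to-maximum time is one respiration period, and the
rate series is 60/period breaths per minute, summarised as mean, sample SD
and RMS. Only maxima are counted as breaths; a convention counting both
maxima and minima would double all rates, and published resting rates near
30 breaths/min are most parsimoniously read under one fixed convention,
which this package states explicitly rather than guessing per dataset.
Rates depend on peak times only, so the indices are amplitude-invariant.

**Facial EMG.** The raw electromyogram is zero-meaned and rectified into a
moving-window RMS envelope (0.1 s window). Corrugator (EMG1) and
zygomatic (EMG2) envelopes form sample-wise ratio series env2/env1 and
env1/env2; the denominator is floored at 1% of that channel's median
envelope to keep rest periods from exploding the ratio. Ratio series of
this kind are heavy-tailed; mean, SD and RMS are reported without any
distributional claim.

**Skin conductance.** The trace is resampled to 32 Hz (amply sufficient
for this slow signal), artifact-reduced by a 0.5 s running median plus
clipping of samples more than 5 robust SDs from the rolling baseline, and
summarised as mean, sample SD and RMS in microsiemens.

For every summarised series the identity RMS² = mean² + population
variance holds by construction and is enforced by tests.

## Group statistics

Subjects are dichotomized at the sample median of the CFI: strictly above
→ High flexibility, strictly below → Low. Scores exactly at the median
alternate between groups in subject order — the published cohort splits
15/15, which any balancing rule reproduces; the alternating rule is simply
stated so ties are deterministic.

Each feature is compared between groups with Student's pooled-variance
t-test. The pooled form (not Welch) is forced by the degrees of freedom
the reference analysis prints (28 = 15+15−2, 25 = 14+13−2). Effect size is
Cohen's d = mean difference over pooled SD. The same routine runs in two
modes: from raw per-subject data, or from per-group (mean, SD, n) triples
— which is exactly what published tables provide — and the two agree to
floating precision when fed matching moments. Per-feature available-case
counts set the degrees of freedom, since which subjects were excluded from
which physiological measure is not recoverable from group summaries. No
multiple-testing correction is applied by default (matching the reference
analysis); Benjamini–Hochberg is available via `adjust = "BH"`.

Normality screening pairs the Kolmogorov–Smirnov normality variant with
estimated mean/SD (the Lilliefors form that statistical suites report) and
Shapiro–Wilk. Results annotate the comparisons; they never gate them.

### A note on the bundled summary tables

`reference_summary_tables()` returns the published per-group summaries
(n, mean, SE, SD) exactly as printed. `summary_se_consistency()` checks
each row for SE = SD/√n, rounding the recomputed SE to the printed number
of decimals before applying a ±0.01 band. All rows pass except the six
skin-conductance rows, where the printed SE equals SD·√n exactly — i.e.
the SE and SD columns are transposed in print. The checker labels these
rows `"transposed"`; `cohort_specs_from_summary()` un-swaps them by
default before parameterizing the cohort sampler.

## Synthetic data: what it emulates, what it does not

The generators exist to carry known ground truth, not physiological
realism:

- `generate_ibi_series()` builds intervals as mean + sinusoidal
  modulations + white noise, accumulating beat times from the intervals
  themselves. A tone at 0.1 Hz with amplitude A places A²/2 ms² of
  tachogram power in the LF band — an analytic target for the spectral
  stage. Sub-millisecond intervals abort generation (over-strong
  modulation drives the accumulated series asymptotically toward zero
  rather than across it).
- `synthesize_bvp()` renders one asymmetric gamma-shaped pulse per beat
  (width 0.3 of the local interval, maximum exactly at the beat time);
  only peak positions matter downstream, so the template shape is
  deliberately minimal.
- `synthesize_respiration()` is a phase-continuous sinusoid with a
  prescribed instantaneous-rate profile; `synthesize_emg()` is Gaussian
  broadband noise times a burst envelope; `synthesize_sc()` is a tonic
  level plus exponential-rise/decay phasic responses.
- `generate_cohort()` draws features independently as Normal(mean, SD²)
  per group from `group_spec`s — the marginal structure that published
  tables pin down. Cross-feature covariance is not asserted (an optional
  correlation matrix exists); consequently, passing tests on synthetic
  cohorts demonstrate correctness of the statistics and the
  classification harness, not claims about the joint distribution of real
  physiological features.
- `generate_rule_cohort()` builds the rule-structured case: a
  respiration-type feature whose high values mark Low flexibility, a
  heart-rate-type feature separating the remainder, value-free gaps
  around both thresholds, and independent noise features. The exception
  subgroup (low respiration feature yet Low-flex) is drawn in the lower
  part of the low band, and the above-threshold subjects' heart-rate
  values straddle their threshold away from its gap; these choices make
  the generating rule the unique optimal tree structure, so recovery is a
  sharp test rather than a coin flip.

All generators are pure functions of (parameters, seed).

## Classification stage

**Ranking.** Each continuous feature is discretized at its
entropy-minimizing binary split (candidate thresholds are midpoints
between consecutive distinct values) and scored by the information gain
of that discretization against the binary label; ties break
alphabetically, constants score zero. A gain-ratio variant divides by the
split entropy.

**LOOCV harness.** Every subject is predicted once by a model trained on
the other n−1. Standardization uses training-fold statistics only — the
held-out subject never influences its own preprocessing. Four learners
are compared under shared defaults: kNN (k = 5, Euclidean, uniform
majority vote, nearest-neighbour tie-break; the AUC score is the
distance-weighted neighbour fraction), RBF SVM (C = 1, Platt-calibrated
probabilities), random forest (100 trees, vote fractions), Gaussian naive
Bayes (posterior probabilities). None of these settings are claimed to
match any particular historical analysis — the original toolkit settings
are unstated — so all are exposed in `classifier_spec()` and fixed by
seed. AUC uses the rank (Wilcoxon) formulation with ties counted half;
CA, precision, recall and F1 come from the 2×2 confusion matrix, the
latter three class-weighted. All metrics are exactly recomputable from
the stored confusion matrix and score list.

**Decision tree.** Greedy binary splits maximizing information gain, the
same split search as the ranking stage; growth stops at pure nodes, fewer
than 2·min_leaf samples, or depth 3 (defaults min_leaf = 2, configurable).
Leaves carry class proportions, and `tree_rules()` prints root-to-leaf
paths as threshold rules on named features.

**A caution on permutation nulls under LOOCV.** On a cohort with strong
cluster structure, permuting labels does *not* push LOOCV accuracy to
0.5: removing the held-out subject removes one member of its own class,
so the training set is always slightly biased toward the opposite class
and within-cluster votes follow. For two tight 15/15 clusters and k = 5
the expected null accuracy is exactly 0.25. The package's null
calibration therefore uses unstructured cohorts (features independent of
labels), where the bias is negligible and mean LOOCV accuracy sits at
0.50. Anyone permutation-testing LOOCV results on clustered data should
expect — and not be alarmed by — below-chance null accuracy.

## Numerical choices

- Resampling: polyphase (rational rate approximation, anti-alias FIR)
  with reflection padding to absorb the filter transient; an FFT
  (spectrum truncation/zero-padding) method is available. Band-limited
  content survives 64× downsampling with < 1% amplitude error.
- Tachogram interpolation: cubic spline; linear available for very short
  or spiky series.
- Welch normalization: one-sided density scaled by the window power, so
  band-power sums reproduce the series variance (Parseval) up to leakage
  — verified within 20% on multi-tone inputs, and within 15% for a single
  LF tone.
- Degenerate inputs: constant interval series give zero SDNN/RMSSD and an
  undefined (NA) Poincaré ratio rather than an error; constant features
  rank with score zero; a flat signal is a detection error; an all-zero
  EMG envelope yields an all-zero RMS envelope.
- Non-finite samples: rejected at load by default, linear-interpolation
  repair on request.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script workloads are sized for quick,
repeatable desk verification while keeping every estimate comfortably
inside its statistical tolerance: 300-beat recordings for extraction
recovery (mean-interval error ≪ 2 ms at 256 Hz), 10,000 simulated
features for type-I calibration (binomial SE ≈ 0.002 around 0.05), 200
permutation replicates for the null accuracy, and 50 replicate cohorts
for rule recovery.

## Known limitations

- Beat detection is built for pulse waveforms with one dominant maximum
  per cycle; it is not an ECG R-peak detector and has no arrhythmia
  handling beyond the plausibility window.
- The HF band's 0.5 Hz upper edge means breathing faster than 30
  breaths/min still folds into HF only up to that edge.
- Skin-conductance processing summarises level; it does not decompose
  tonic and phasic components.
- The synthetic cohorts inherit only the published marginal moments;
  conclusions about real multivariate physiology require the real
  recordings.
- With n ≈ 30, LOOCV metrics have large variance; the package reports
  them faithfully but nothing in the design mitigates small-sample
  optimism beyond the leakage-free standardization.
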