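---
title: "Degradation-filter synthesis and the personal beat classifier: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degradation-filter synthesis and the personal beat classifier: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abswarn)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic data generator does and does not emulate, and the design
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The problem

Patient-specific ECG classifiers outperform population models because
normal ("N") beat morphology varies enormously between people — one
person's normal beat can resemble another's ventricular ectopic. But a
patient-specific classifier normally needs annotated *abnormal* beats
from its patient, and a healthy person has none. The package's premise is
that the common causes of arrhythmia can be modeled *in the signal
domain* as degradations that turn normal beats into abnormal ones, that
these degradations transfer across people, and that a person's potential
abnormal beats can therefore be synthesized before any ever occurs.

## Beat representations

Every beat is reduced to 128 samples in two complementary ways:

* **single**: `half_window` raw samples each side of the annotated R peak
  (default 0.35 s × fs ≈ 126 samples at 360 Hz — wide enough to span
  P–QRS–T at normal rates), linearly resampled to 128 so the R peak lands
  at index 64. This channel carries morphology.
* **trio**: the span from the previous beat's window start to the next
  beat's window end, resampled uniformly to 128. Because the resampling
  is uniform over the whole span, relative timing survives: a premature
  center beat sits left of its neighbors' midpoint. This channel carries
  rhythm, and is what makes supraventricular ectopy — often
  morphologically identical to N — detectable.

Linear interpolation was chosen as the resampling method because it is
deterministic, endpoint-preserving, exactly the identity for
already-128-sample windows, and trivially checkable against a brute-force
oracle; a polyphase FIR resampler is available behind an option for
strongly oversampled segments. Windows crossing the record boundary are
zero-padded with a warning rather than dropped, keeping beat counts
stable; first/last beats have no trio and are excluded from trio
datasets. Sample indices are 0-based in all interchange formats. No
per-beat amplitude normalization is applied by default.

The **average normal beat** (ANB) of a subject is the *real* N beat whose
single representation is closest (Euclidean) to the pointwise mean of all
N beats in the first five minutes; ties go to the earliest beat. Using a
real beat rather than the mean avoids the low-pass blurring of averaging.
Candidates are restricted to beats that possess a trio, since the ANB
must exist in both representations.

## Degradation filters

One FIR kernel models one normal-to-abnormal degradation. With `A` the
128×M convolution matrix of the ANB (same-length, center-tap aligned,
zero-padded borders — so the filter output is directly comparable to a
128-sample target) and `b` the abnormal beat,

$$\hat h = \arg\min_h \;\lVert b - A h\rVert^2 + \lambda \lVert h\rVert^2$$

solved in closed form via the regularized normal equations
(`solve(AᵀA + λI, Aᵀb)`), with a minimum-norm pseudoinverse fallback when
λ = 0 meets a singular system. Tikhonov ridge is the canonical reading of
"regularized least squares" and keeps the solver closed-form and
deterministic; λ is exposed (`filter_design_config`, default `1e-3` —
small enough that fit residuals are visually indistinguishable from the
unregularized fit, large enough to stabilize coefficients when the ANB
spectrum has nulls). The default M = 32 taps (a quarter of the beat
length) keeps the 128-equation system strongly over-determined while
leaving enough support to reshape QRS and T morphology; residuals are
non-increasing in M by nesting, which the tests assert.

Curation applies three rules, in order, per donor subject:

1. **All-pass exclusion.** If `‖b − a‖/‖a‖ < 0.15` the abnormal beat is
   essentially the ANB (typical of S beats in the single representation,
   whose anomaly is purely timing) and a filter would merely reproduce
   normal beats; it is skipped. The test operates on beats, not designed
   filters — cheaper and closer to what it means.
2. **Deduplication.** Filters whose coefficient vectors correlate above
   0.95 are clustered greedily in `(fit_residual, subject, id)` order and
   each cluster keeps its best-fitting member, making the result
   order-independent.
3. **Distinctness.** Pooled filters are ranked by coefficient variance
   (the most "active" degradations) and the top k kept; the default keeps
   all survivors, k exists to emulate fixed-size libraries.

The similarity thresholds are package choices — the source protocol
leaves them unstated — and both are exposed in `curation_thresholds()`.

For monitoring, `exclude_subject()` removes a person's own filters from
the library before synthesis, so evaluation is leave-subject-out: the
classifier never benefits from degradations learned from the very
arrhythmias it is asked to detect.

## The personalized training set

Real part: every N beat (both representations) from the subject's first
five minutes. Synthetic part: the excluded library applied to the
subject's ANB; each filter contributes one item labelled with its source
class, flagged synthetic. The constructor enforces the core invariant —
no real abnormal beat, and no synthetic N beat, can enter a training set.

Filters live per representation mode, and curation is mode-specific, so
the two mode libraries need not contain the same filters. Items are
paired by filter id (donor subject + donor beat): a filter retained in
both modes contributes both synthetic channels; a filter surviving only
in trio mode — e.g. a timing-only S beat whose single representation was
all-pass — contributes the subject's own single-mode ANB as the missing
channel, which is precisely the physiology (the morphology *is* normal);
symmetrically for single-only filters.

**Common training data.** Donor records also contribute a deterministic
selection of real N beats (default 30 per donor; the monitored subject
is never its own donor). This matters for a subtle reason: a monitored
person's first five minutes contain only evenly spaced N beats, so an N
beat whose trio contains a neighboring ectopic and its compensatory
pause is a window type the classifier has otherwise never seen labelled
N — and in development exactly those windows accounted for essentially
all false alarms (49 of 50 in the diagnostic run). Donor records, which
do contain arrhythmias, supply such windows with the correct label; the
selection therefore prefers ectopic-adjacent donor N beats (two thirds
of the per-donor budget, evenly spaced over the candidates) and fills
the rest with evenly spaced plain N beats. Per-class caps and
N-subsampling for class balance exist but are off by default.

## The personal classifier

A deliberately tiny two-channel 1D CNN:
input 2×128 → conv(7, valid)→122 → avg-pool(3)→40 → conv→34 → pool→11 →
conv→5 → global avg-pool→1 → FC 16→32 → FC 32→5, tanh throughout, with
32/16/16 conv neurons. The global average pool of the last conv stage
makes the fully-connected input width independent of the input length;
layer arithmetic is asserted at construction and recomputed if kernel or
sub-sampling change. Targets use the ±1 encoding matched to the tanh
range; the loss is squared error. Average pooling is the default
(differentiable everywhere, classical for this network family); max
pooling is available behind a flag.

Training is *shallow* by design, to avoid over-fitting a set whose
abnormal half is synthetic: at most 50 back-propagation iterations, a 3%
train classification-error floor, learning factor ε starting at 0.001
and multiplied by 1.05 after an iteration whose MSE decreased (the first
iteration counts as a decrease), by 0.70 otherwise; the ε recorded for an
iteration is the one its sweep used, so a history can be audited against
its MSE trace exactly. Ten runs from consecutive seeds are trained per
person and their confusion matrices cumulated.

Two design points deserve their rationale:

* **Per-sample sweeps, not full-batch steps.** One BP iteration is one
  pass over the training set in a seeded shuffled order, applying each
  item's squared-error gradient immediately. A full-batch step at
  ε = 0.001 moves the weights by ~10⁻⁴ per iteration — fifty of them
  cannot leave the majority-class region — while scaling the batch
  gradient up instead produces oscillatory collapse; the per-sample
  formulation is the classical one for this network lineage and trains
  reliably at exactly the stated ε and iteration budget. Determinism is
  preserved: the shuffle orders are a pure function of the seed.
* **Fan-scaled initialization.** Weights start uniform in ±√(6/(fan_in +
  fan_out)) per layer, biases uniform in ±0.1. A flat small init (e.g.
  ±0.1 everywhere) attenuates the signal about a hundredfold across the
  five tanh stages, leaving fully-connected-input features with a
  standard deviation of ~10⁻³; no configuration of the stated optimizer
  escapes the majority class from there. Fan scaling keeps activation
  variance roughly constant through depth, which is what makes the small
  learning factor sufficient.

The per-sample sweep is implemented twice: a compiled kernel
(`src/train.cpp`) used by default, and a pure-R reference engine
(`train_cnn(engine = "r")`) with identical arithmetic; the tests assert
their equivalence to machine precision, check analytic gradients of
every layer type against central differences, and check the vectorized
forward pass against an unvectorized loop oracle.

## Evaluation

The 5×5 confusion matrix (rows truth, columns prediction, order
N, S, V, F, Q) is cumulated over the ensemble — each beat counted once
per model — then collapsed to Normal-vs-Abnormal (tn, fn, fp, tp; any
abnormal class predicted for a true abnormal beat is a true positive:
the task is detection, not typing). Metrics follow the standard
definitions; a metric whose denominator is zero (e.g. sensitivity for a
subject with no abnormal beats) is reported `NA`, never 0, and such
subjects are the cleanest probes of the real false-alarm rate. Pooling
across subjects sums matrices before computing metrics.

The advance-warning figures treat consecutive abnormal-beat detections
as independent: `p_miss1 = fn/(tp+fn)`, `p_miss3 = p_miss1³`,
`P(detect within 3) = 1 − p_miss3`. The report also carries the
3-decimal truncation of `p_miss1`, a common printed rendering.

## The synthetic cohort generator

Beats are sums of five Gaussian bumps (P, Q, R, S, T; amplitudes in mV,
centers in seconds relative to the R peak, widths in seconds), with
defaults sketching a modified-lead-II normal beat (P 0.15 mV at −0.20 s,
narrow dominant R of 1.0 mV, Q/S troughs, broad T of 0.35 mV at 0.25 s).
A subject is a one-time jitter of amplitudes and widths (fractional sd
0.10) plus a heart-rate draw around 70 bpm — inter-patient variation —
and each beat adds a smaller jitter (sd 0.02) plus white noise
(sd 0.01 mV). Class phenomenology follows AAMI convention:

* **V**: QRS widths ×2.5, P suppressed, discordant T, premature
  (RR ×0.78) with a compensatory pause that conserves the two-beat span;
* **S**: near-normal morphology (P ×0.85) but premature (RR ×0.70) with
  compensatory pause — detectable only through the trio channel;
* **F**: convex blend (weight 0.5) of the subject's N and V shapes;
* **Q**: randomized per-beat amplitudes and widths.

All randomness flows through seeds passed explicitly; identical seeds
give byte-identical records. The default cohort — the study conditions
for the end-to-end tests — is 5 training subjects of 600 beats with
S/V/F beats throughout, and 3 test subjects whose first five minutes are
all-N (380 beats) followed by a 240-beat monitored tail containing at
least 20 abnormal beats. Problem sizes were chosen so the complete
pipeline (library → synthesis → 10-run ensembles → monitoring) is a
desk-scale computation; a sum-of-Gaussians model was preferred over a
dynamical-system ECG simulator because it is analytic, seedable and
produces exactly the class contrasts the method needs.

What the generator does *not* emulate — and hence what passing tests do
not show about clinical data: baseline wander, electrode motion and
muscle artifact; heart-rate drift and respiratory sinus arrhythmia;
morphology nonstationarity within a record; the long-tailed diversity of
real ectopic shapes; and annotation errors. Synthetic subjects are
"easier" than MIT-BIH patients in all these respects, and the end-to-end
detection numbers on the synthetic cohort should be read as a
correctness check of the machinery, not a clinical performance claim.

## Numerical choices and degenerate inputs

* Resampling agrees with the linear-interpolation oracle to 10⁻⁹;
  segments must have ≥2 samples.
* Ridge systems are solved by `solve()`; singular λ = 0 systems fall
  back to the pseudoinverse and the filter is flagged.
* Pearson correlation of constant coefficient vectors is undefined;
  deduplication treats two constants as identical only if numerically
  equal.
* Argmax ties in prediction go to the lowest class index; ANB ties to
  the earliest beat; curation ties to (subject, id) order — everything
  is deterministic.
* Empty library → training set flagged single-class; training refuses
  single-class sets with an explicit message; a cohort without abnormal
  beats yields an empty library, not an error; an all-N monitored
  subject reports FAR only.
* Serialization (filters, training sets, models) is plain text — JSON
  with 17 significant digits or CSV printed with `%.17g` — which
  round-trips IEEE doubles bit-exactly.

## Known limitations

* Linear FIR degradations cannot displace a single beat within a trio
  (convolution shifts the whole window), so synthetic trio-mode abnormal
  beats approximate real premature-beat timing imperfectly; the trio
  channel consequently contributes more to separating rhythm anomalies
  than to reproducing them faithfully.
* With few donors the library may not span a given subject's abnormal
  morphologies; per-subject sensitivity then varies widely even when the
  pooled advance-warning probability is high. The reference protocol's
  donor pool (20 records) is four times the default synthetic one.
* The operating point of the trained classifiers varies between cohorts:
  some seeds produce conservative ensembles (high specificity, moderate
  sensitivity), others hypersensitive ones whose false alarms concentrate
  on the ectopic-adjacent N windows discussed above. Common training
  data narrows but does not close this gap, because a monitored
  subject's own ectopic-adjacent windows contain that subject's own
  abnormal morphology as the neighbor — a window that could only be
  covered by synthesizing *context* windows, which lies outside the ABS
  mechanism this package implements.
* The miss-probability model assumes independent consecutive detections;
  correlated misses (e.g. one ectopic focus producing identical beats)
  would make `p_miss3` optimistic.
* The 3% error floor is evaluated on a training set whose abnormal half
  is synthetic; it bounds over-fitting but is not a validation error.
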