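---
title: "Recognizing activities of daily living against a dominant NULL class"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing activities of daily living against a dominant NULL class}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristadl)
```

## The problem

A person wears a watch on each wrist through an ordinary day. Almost all of
the resulting accelerometer stream is background — the `NULL` class — and
the seven activities of daily living (ADLs) we want to detect occupy a few
percent of the time, in events lasting seconds to minutes. Two consequences
drive every design choice in this package:

1. **Window-level classification is imbalanced to an extreme degree.** With
   per-class imbalance ratios `IR_a = (n - |C_a|)/|C_a|` in the hundreds, a
   classifier that maximizes window accuracy simply predicts `NULL`.
2. **Window-level metrics are not what a deployment cares about.** A
   caregiver wants to know whether a tooth-brushing *event* happened, not
   whether 73% of its one-second windows were labeled correctly. We
   therefore score at the event level throughout.

## Windows and features

Streams are segmented with a 1 s sliding window at 75% overlap, i.e. a
0.25 s stride; a stream of duration `T` yields `floor((T - 1)/0.25) + 1`
windows. Window starts sit at exact multiples of the stride and each
window's sample slice is rounded independently, so the count formula holds
at any sampling rate (including rates where the stride is a non-integer
number of samples). Each window's label is the majority per-sample label,
with ties resolved in favor of a non-`NULL` activity and, among tied
activities, by the label at the window's center sample — a rule that mildly
favors recall of the rare classes.

Each window yields 106 features: 17 per accelerometer axis per hand and 2
per hand. Several feature names in the underlying feature set are standard
but not accompanied by formulas; the definitions adopted here are:

- *Average jerk*: mean absolute first difference times the sampling rate.
- *Peaks and valleys*: local extrema with prominence at least 0.1 times the
  window standard deviation (a flat window has none). The "average/SD of the
  number of peaks" features are the mean and SD of peak counts over the
  window's four equal non-overlapping quarter-segments.
- *Average height / SD height*: mean and SD of the signal values at detected
  peaks; 0 when no peaks exist.
- *Energy*: mean squared deviation from the window mean. *Entropy*: Shannon
  entropy of the normalized one-sided DFT magnitude distribution.
- *Spectral centroid / spread / rolloff* are computed on one-sided DFT
  magnitudes with the DC bin excluded (bins `k = 1..N`); the rolloff is the
  smallest bin reaching 85% of the cumulative magnitude. An all-zero (or
  numerically zero: spectral mass below 1e-9 of the signal mass) spectrum
  returns centroid = spread = 0 and rolloff = 1, never NaN.
- *Axis overlap* (per hand): the number of pairwise crossings among the
  three axis traces, divided by the window duration — a measure of how
  interleaved the axes are.
- *Fractal dimension* (per hand, on the acceleration norm): box-counting
  slope of `log N(eps)` vs `log(1/eps)` over a dyadic grid of scales on the
  curve rescaled to the unit square, clamped to [1, 2]; constant or
  too-short signals return 1.

The sampling rate of the original hardware is not part of the published
design; the loader resamples to a configurable uniform rate (default 50 Hz)
by linear interpolation, which keeps window sample counts constant.

## Imbalance treatments

Three standard treatments are applied to the *training split only*, after
feature extraction (resampling validation or evaluation data would corrupt
the measurement):

- **RUS**: the majority class is sampled without replacement down to exactly
  the total non-majority count.
- **Ratio-preserving ROS**: minority rows are duplicated with replacement so
  the minority total equals the majority count while pairwise minority
  ratios are preserved. Balancing every class to the majority size would
  impose a near-uniform prior on classes whose true frequencies differ by an
  order of magnitude; preserving ratios avoids that. Integer targets come
  from largest-remainder apportionment, which hits the total exactly with at
  most one unit of ratio distortion.
- **CSL**: balanced class weights `w_c = n/(k * n_c)`. Naive Bayes has no
  concept of class weights and rejects them.

## Window classifiers

Gaussian naive Bayes, random forest (100 trees, depth 30), SVM-RBF, and
XGBoost (100 rounds, depth 30, multiclass softmax) — `ranger`, `e1071` and
`xgboost` behind a uniform train/predict surface. The SVM's regularization
is not part of the published configuration, so `cost = 1` and
`gamma = 1/n_features`, documented and configurable. Features are z-scored
with training-split statistics for the scale-sensitive learners (SVM, NB);
tree ensembles consume raw features. Fitted models store their feature
schema and label set and refuse mismatched inputs.

## Context-based correction

A prediction stream is an ordered label sequence at the window stride. The
correction replaces each prediction with the winner of a weighted vote over
the `ws` predictions around it; weights decay with the distance `d` from the
context midpoint `floor(ws/2) + 1` under one of five functions (with
`h = ceiling(ws/2)`): `W1 = max(h-d, 0)`, `W2 = 1/(d+2)`,
`W3 = max(h-d, 0)^2`, `W4 = log(max(h-d, 0)+1)`, `W5 = 1/log(d+2)`.

Numerical and semantic choices:

- **Distance convention.** The literal streaming formulation uses the signed
  offset `i - midpoint + 1`, which would make the triangular weight
  asymmetric within the context. Because the weight is defined as a function
  of the *distance from the window center*, the default uses `d =
  |i - midpoint|`; the signed form remains available behind `signed_d`.
- **Alignment.** The streaming formulation emits the correction of the
  *trailing* context, lagging the stream. The default `centered` mode
  assigns each position the correction of the context centered on it —
  scoring a corrected stream against ground truth presupposes this
  alignment. `literal_streaming` mode reproduces the lagging behavior
  (warm-up pass-through of the first `ws` outputs, then trailing-window
  corrections), which is what an on-line deployment would emit.
- Negative triangular weights at extreme offsets of even-sized contexts are
  clamped to 0: votes accumulate evidence, and negative evidence is not part
  of the scheme. Logs are natural; the argmax is invariant to the base
  (asserted on random streams).
- Ties are broken by the higher raw label count in the context, then by
  earliest first appearance; positions whose full centered context falls
  outside the stream pass through unchanged; a context longer than the
  stream passes the whole stream through with a warning.
- Context sizes are specified in seconds and converted via the stride
  (`ws = round(ws_s/stride)`, so 160 s at a 0.25 s stride is 640
  predictions, and `ws = 1` is the identity).

The choice of `ws` trades off insertion removal against event erasure: a
centered vote erases genuine events much shorter than about half the
context. Large contexts (160 s) suit recordings whose events run minutes;
for the reduced-scale synthetic streams used in the examples (events of
20–90 s) a 30 s context is the principled choice — no event class is
shorter than about two-thirds of the context.

## Event-level scoring

Maximal same-label runs are events (half-open `[start, end)` in stride
units). Per ground-truth event: Deleted (no overlapping prediction),
Fragmented (two or more overlapping predictions), Merged (an overlapping
prediction also covers another ground-truth event), both, or Correct. Per
predicted event: Insertion, Fragmenting, Merging, both, or Correct; the two
Correct tallies agree by construction, and the category sums equal the event
totals on each side (asserted on every call). Overlap means sharing at least
one frame; a minimum-overlap fraction is available but off by default, since
the category definitions are stated in terms of any overlap.

Event precision is `1 - I'/n_pred` and recall `1 - D/n_gt` — fragmenting
and merging returns count as positives. When one side has no events, the
affected metric is 1 if the other side is also empty, else 0. The single
pooled number reported for a multi-class stream sums category counts across
activity classes before applying the formulas (micro pooling — the only
reading that yields one number from per-class categories without extra
weights); a macro average over classes is also emitted, as are window-level
macro precision/recall/F1 over all classes including `NULL`. `NULL` is
background, not an event class.

## The synthetic generator

The generator exists to exercise the pipeline under the imbalance structure
of in-the-wild recordings, not to imitate biomechanics. Each class is an
oscillatory signature — a class-specific frequency (1.1–4.5 Hz) and
amplitude on the dominant hand (both hands for walking and hand-washing),
log-normal durations, and a Poisson events-per-hour rate. Events are placed
uniformly with a non-overlap constraint (rejection sampling with a retry
cap); the background is Gaussian noise plus unlabeled "distractor" motion
bursts. The default signature rates and durations imply per-class imbalance
ratios between roughly 40 and 520, matching the magnitude of the motivating
study, and the default configuration mirrors its design at reduced scale:
nine participants recording 3–12 h each at 50 Hz.

What passing tests on this generator do show: the feature representation
separates distinct oscillatory classes; resampling and class weights shift
the recall/precision balance the way imbalance theory predicts; context
correction removes short spurious events. What they do not show: performance
on real recordings, where classes overlap through shared motions (drinking
vs. eating), intraclass variability is high, and the background contains
structured activity resembling the classes.

A separate corruption model (`corrupt_predictions`) emulates window
classifier error modes directly on label streams — per-step misses, spurious
insertions with geometric run lengths, and fragmentation holes — so the
correction and scoring layers can be tested without training anything.

## Problem sizes in the tests and acceptance script

The packaged checks run the generator at deliberately reduced scale, chosen
as the smallest worlds in which every class appears and event counts support
directional comparisons: a clean 4-participant world (45 min each, 20 Hz,
events of 20–90 s at 1.5 events/h per class, ~85% NULL) for end-to-end
recovery, and a harder 5-participant world (1 h each, activity amplitudes
scaled to the background noise level, long 100–200 s events at 0.7 events/h)
in which the classifier genuinely misses rare events, so that oversampling
demonstrably raises event recall at a precision cost and a 160 s context
correction recovers precision and F1. Directional claims are asserted under
fixed seeds; they reproduce the qualitative pattern of the motivating
experiments, not their absolute numbers, which would require the original
restricted dataset.

## Known limitations

- The per-axis feature definitions labeled "interpretation" above (peak
  height, quarter-segment peak statistics, axis overlap) are reasonable
  readings of underspecified feature names; other readings would change
  feature values but not the pipeline's structure.
- The greedy participant-stratified splitter minimizes per-class ADL-hour
  deviation from the target fractions but is not guaranteed optimal; it
  matches the exhaustive optimum on small instances in the tests.
- Gyroscope channels are carried through ingestion but excluded from the
  classical feature set by design.
- The generator's signatures are stationary sinusoids; it cannot produce
  the class-overlap failure modes of real consumption activities (eating /
  drinking / taking medication), and results on it are accordingly
  optimistic.
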