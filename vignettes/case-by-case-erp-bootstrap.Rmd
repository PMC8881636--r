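---
title: "Case-by-case bootstrap analysis of ERP emotional modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-by-case bootstrap analysis of ERP emotional modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpcase)
```

## The problem

Emotional modulation of event-related potentials (ERPs) is classically
demonstrated at the group level: high-arousing pictures evoke a relative
negativity over temporo-occipital sensors at roughly 150-350 ms (the early
posterior negativity, EPN) and a relative positivity over centro-parietal
sensors at roughly 350-750 ms (the late positive potential, LPP), compared
with low-arousing control pictures. A group mean, however, describes a
hypothetical average person. The case-by-case approach asks instead: does
*this* participant show the effect? With several hundred trials per
condition, the participant's own trials become the resampling unit, and a
within-subject bootstrap provides an exact-rate significance test without
any across-subject assumptions.

`erpcase` implements that analysis as a reusable pipeline: a synthetic
epoched-EEG generator that emulates the study design, the preprocessing
chain, cluster-mean component scoring with fixed or individually adapted
time windows, the 50,000-replicate bootstrap test with graded p-criteria, a
bootstrap signal-to-noise quality gate, a mirrored-stimulus specificity
(false-alarm) analysis, and group-level statistics.

## The single-subject test

For one subject, one behavior system, and one component, let
$x_1,\dots,x_{n_H}$ and $y_1,\dots,y_{n_L}$ be the per-trial scores: each
trial's mean amplitude over the component's sensor cluster and scoring
window. The observed statistic is
$d = \bar{x} - \bar{y}$ (high minus low arousal, in microvolts). The null
distribution is built by pooling all $n_H + n_L$ scores and, in each of
$B$ replicates, drawing $n_H$ pseudo-high and $n_L$ pseudo-low scores with
replacement and recording the difference of their means. The one-sided
p-value is the proportion of replicates at least as extreme as $d$ in the
component's predicted direction (negative for EPN, positive for LPP), with
equality counting as extreme and no continuity correction: $p = c/B$.
With $B = 50{,}000$ the graded criteria $p < .05, .025, .01, .001,
.00002$ correspond to fewer than 2500, 1250, 500, 50 and 0
equal-or-more-extreme replicates (`criterionCountBound()`).

Two conventions worth making explicit:

* **Equality and floating point.** "Equal or more extreme" includes
  equality; to keep that meaningful in floating point, the comparison
  allows a 1e-9 microvolt slack.
* **Trial-order invariance.** The pooled scores are sorted before
  resampling, so the p-value depends on the data only through the pooled
  multiset and the two counts; permuting or relabeling trials leaves every
  result unchanged under a fixed seed.

## Window selection

In **fixed** mode the scoring windows are the group-analysis windows:
EPN 240-300 ms, LPP 380-480 ms. In **adaptive** mode the window of the
component's span (EPN 60 ms, LPP 100 ms; in samples,
`round(span * fs/1000) + 1` with inclusive endpoints) is slid in 1-sample
steps across the component's search range (EPN 150-350 ms, LPP
350-750 ms) over the cluster-mean high-minus-low difference series, and
the window maximising the direction-signed mean is selected; ties break to
the earliest start. Selection operates on the cluster-mean series — the
same quantity used for scoring — not on per-sensor maxima.

Because the observed window is chosen to maximise the observed effect, a
test that reuses that window for every bootstrap replicate (the
`fixed_observed` policy, the default) is anti-conservative under the null.
This is a property of the procedure being modelled, not a defect of the
implementation: the package's null calibration reproduces it
quantitatively (fixed windows reject at the nominal 5%; adaptive windows
reject at roughly 3x that rate), and it is the mechanism behind elevated
false-alarm rates in mirrored-stimulus specificity analyses. The
alternative `reselect_per_replicate` policy re-runs the window search
inside every replicate, which restores calibration at a considerable
computational cost; it is provided for methodological comparison because
the original procedure's choice between the two is not documented.

## Preprocessing

The chain is: band limiting, baseline adjustment, average reference,
artifact rejection, trial-count equating.

* **Filters.** Butterworth low-pass with half-power cutoff 40 Hz
  (order 19) and high-pass with half-power cutoff 0.06 Hz (order 4). An
  order-19 IIR filter is numerically unusable as a single transfer
  function in double precision, so filters are designed analytically as
  cascaded second-order sections via the bilinear transform with cutoff
  prewarping; the contract is the magnitude response (exactly -3 dB at
  each cutoff), which the tests verify. The default phase mode is
  zero-phase (forward-backward) because scoring uses window means, which a
  causal filter's group delay would bias toward later latencies; a causal
  mode is available. Whether the original analysis filtered causally or
  zero-phase is not documented, hence the configurable choice.
* **Baseline and reference order.** Per trial, the mean over the
  pre-stimulus baseline (half-open [-100, 0) ms) is subtracted per sensor
  first; the across-sensor mean is subtracted per sample second. The two
  orders differ only by a per-trial constant, but this order makes both
  identities hold simultaneously: after the operation the across-sensor
  sum is exactly zero at every sample *and* the per-sensor baseline mean
  is exactly zero. The original description states both steps but not
  their order.
* **Artifact rejection** is a plain absolute-amplitude threshold (default
  100 microvolts): the dense-array statistical artifact-control method
  used for the original recordings is a separate published procedure, out
  of scope here.
* **Trial equating** keeps a seeded random subset of the larger condition
  so both conditions enter the bootstrap with equal counts, preserving
  original trial order among kept trials.

## The synthetic-data generator

`generateStudy()` emulates the study design so the whole pipeline is
testable without recordings: per subject and behavior system, 600 trials
per picture category at 250 Hz, epochs -100..800 ms, balanced left/right
mirror labels within condition, three behavior systems. The per-trial
model is additive:

* **Noise**: spatially correlated $1/f^\beta$ noise (default $\beta = 1$),
  built as a shared across-sensor trace plus sensor-specific traces mixed
  by `spatialCorr` (default 0.3), each trace normalised to SD `noiseSd`
  (default 20 microvolts). Nothing about the original recordings' noise
  structure is published; spatial coherence is included because
  cluster-mean standard errors would otherwise be unrealistically small at
  41-sensor cluster sizes.
* **Base ERP**: a condition-independent broad bump (default 4 microvolts,
  50-650 ms), positive-going on the posterior cluster and negative-going
  on the central cluster, matching the typical polarity of posterior vs
  central ERPs and giving the SNR gate a real signal to measure.
* **Effects**: Hanning bumps added on high-arousal trials — an EPN-like
  negativity on the posterior cluster (default peak -3.3/-2.4/-1.5
  microvolts for the three systems, centre 270 ms, span 120 ms) and an
  LPP-like positivity on the central cluster (default +3.0/+1.9/+0.9,
  centre 430 ms, span 160 ms), with per-trial latency jitter (SD 10 ms)
  and amplitude scatter (SD 1 microvolt). The Hanning shape is smooth,
  compactly supported, and analytically integrable, so closed-form oracle
  checks are possible. Per-system defaults descend from the relative
  ordering observed for sexual-reproduction, disease-avoidance and
  predator-fear materials; `noiseSd` is calibrated only so that
  between-subject effect sizes land near Cohen's d of 2 — single-trial
  noise magnitudes of the original recordings are not published, so the
  generator makes no claim to match them.
* **Between-subject variation**: per subject x system x component, effect
  amplitudes are scaled by a unit-mean lognormal factor (log-SD 0.45).
* **Mirror labels carry no signal** by default, making them a built-in
  null for the specificity analysis; `mirrorEffectAmp` can inject a
  mirror-locked effect to test specificity power.
* **Seeding**: one root seed; child seeds per (subject, system, purpose)
  derive from a fixed counter scheme, so any single case regenerates
  bit-identically without generating the rest of the study.

What the generator deliberately does not emulate: ocular artifacts, bad
channels, non-stationary noise, sensor-geometry-specific covariance, or
continuous (pre-epoched) recordings. Passing tests therefore demonstrate
the statistical machinery under the stated noise model, not robustness to
every property of real EEG.

## Signal-quality gate

Two tools mirror the original quality checks. `plusMinusErp()` averages
trials with alternating polarity, cancelling the evoked signal and leaving
the residual noise level of the average. `snrCi()` draws, per replicate,
n_min trials with replacement (n_min = the smaller condition count),
averages them, and computes `20*log10(RMS(post-stimulus) /
RMS(pre-stimulus))` of the cluster-mean waveform; the 90% central
percentile interval of the replicate dBs is the CI, and a case passes when
the lower bound reaches 3 dB. Conventions chosen where the source method
leaves room: dB is 20 log10 of the amplitude (RMS) ratio; the
post-stimulus window defaults to the full post-onset epoch; the CI flavor
is percentile; resampling ignores condition labels, since the gate
measures signal quality, not condition effects. One caveat the tests make
explicit: the CI width does *not* shrink towards zero with more trials —
it asymptotes to the spread contributed by the finite pre-stimulus window
— so the width-vs-trials property is tested in the regime where trial
noise still dominates the post-stimulus RMS.

## Specificity and study tables

`runSpecificity()` scores left vs right mirrored presentations of the same
picture category with the same parameters as the main analysis, testing
both directions; with two categories this gives four tests per component,
and the percentage of significant tests per criterion is the false-alarm
rate (100 - specificity). In fixed mode the two directional tests reuse
one bootstrap distribution (the statistics are sign flips of each other);
in adaptive mode the window is selected per direction, so each direction
gets its own distribution — whether the original software shared one null
distribution is not documented.

`sensitivityTable()` and `falseAlarmTable()` tabulate nearest-integer
percentages (ties away from zero, so 14/16 prints as 88 and 15/16 as 94).
Cochran Q compares proportions of significant cases across criteria or
systems, with pairwise exact McNemar tests under Bonferroni correction as
post hocs (the original post hoc procedure is unnamed; pairwise McNemar is
the standard reading). The half-split habituation reanalysis splits trials
by original order within condition, giving the extra trial of an odd count
to the first half. Group tests are dependent t-tests on fixed-window
scores with Cohen's d = mean/SD of the paired differences.

## Numerical and design choices, collected

* Window endpoints are inclusive; a 60 ms window at 250 Hz holds 16
  samples. Adaptive ties break to the earliest start.
* Degenerate inputs error loudly: effect supports outside the epoch or
  search range (by component name), empty baseline or scoring windows,
  cutoffs at or above Nyquist, epochs too short to filter stably, all
  trials rejected, zero pre-stimulus RMS.
* p = count/B exactly, so "0 out of 50,000" is p = 0, reported against
  the p < 0.00002 criterion.
* Sample indexing is 1-based in R; time 0 is stimulus onset and is sample
  `tZeroIndex` of the epoch.
* The shipped cluster files are the published 41-sensor occipito-parietal
  and 40-sensor centro-parietal definitions for the 256-lead geodesic
  net; the latter includes channel 257 (the vertex reference), so
  montages of 257 channels address it directly and 256-channel montages
  drop it.

## Simulation sizes used by the test suite

The statistical checks run at desk scale, chosen to finish on one CPU
while keeping Monte-Carlo error well inside the asserted bands: null
calibration uses 500 effect-free subjects (16 sensors, 100 trials per
condition, B = 2000; both window modes scored on the same subjects);
power/window-recovery uses 100 subjects at 600 + 600 trials with an
injected EPN effect of 4 standard errors (the injected amplitude divides
out both the mean Hanning weight over the scoring window and the
average-reference attenuation — subtracting the across-sensor mean scales
a k-of-n-sensor cluster-confined effect by 1 - k/n — so that the
post-preprocessing window-mean difference, the quantity whose SE is
estimated, really is 4 SE); SNR coverage uses 100 subjects.
The full-design defaults (256 sensors, 600 trials per condition, three
systems, B = 50,000) remain the generator's and the bootstrap's defaults
and run unchanged, just longer.

## Limitations

* The generator's noise model is stationary and Gaussian; real EEG is
  neither, and real false-alarm rates may differ from the simulated ones.
* The adaptive-window inflation reproduced here is qualitative: its size
  depends on search-range width, span, and noise autocorrelation, so it
  is tested as a direction (above nominal), not as a specific percentage.
* Spatially adaptive (sensor-searching) scoring is not implemented; the
  sensor clusters are fixed a priori.
* The SNR dB convention (20 log10 of the RMS ratio) is declared, not
  inherited from the cited method's implementation.
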