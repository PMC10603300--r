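---
title: "Predicting bimanual coupling from EEG: models, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting bimanual coupling from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When the two hands draw different shapes at once — a vertical line with one,
a circle with the other — each movement distorts the other: lines bulge,
circles flatten. The per-trial strength of this interference is summarised
by a coupling index computed from the drawn shapes, and the scientific
question is which representation of simultaneously recorded motor-cortical
EEG predicts that index trial by trial:

* **univariate** — event-related desynchronization (ERD), one value per
  channel and frequency band;
* **distributed univariate** — magnitude-squared coherence between pairs of
  motor channels, averaged within channel groups;
* **multivariate** — a shallow feedforward network over the full
  band-resolved time-frequency pattern of all nine motor channels.

Because no public recording of this task exists, the package pairs the
analysis chain with a synthetic session generator whose ground truth is
known, so the chain's central contrast — *a distributed nonlinear code is
invisible to every univariate readout but recoverable by the network* — is
a falsifiable, testable property rather than an anecdote.

## Behavioural model

Each trial: both hands draw 6 iterations of their condition's shape
(`line-line`, `circle-circle`, `line-circle`, `circle-line`). Curvature of
a drawn shape is its horizontal extent `C = |max(x) - min(x)|` in pixels
(lines are drawn vertically, so an ideal line has `C = 0`), pooled over all
samples of the trial. The coupling index is

\[ \mathrm{CI}_t = \frac{1}{\max(|C_{t,\mathrm{left}} - C_{t,\mathrm{right}}|,\ \mathrm{floor})} \]

The reciprocal-difference form is singular at equal curvatures, so a floor
is required. Its default is 3 px: with pixel-level pen jitter the extent of
each hand is only determined to a couple of pixels, so differences below
~3 px are indistinguishable from measurement noise, and treating them as
real would let a handful of coincidentally-equal trials dominate every
downstream correlation through the reciprocal's tail (CI would span three
orders of magnitude, with its variance owned by its top two or three
values). The index is symmetric in the hands and strictly decreasing in
the curvature difference — larger values mean more similar shapes, i.e.
stronger coupling. Curvature is pooled over all six iterations rather than
averaged per iteration; with extents, pooling and averaging differ only
through slow drift, and pooling is the simpler reading of "the shape".

## The synthetic session

Defaults are the study conditions the pipeline is built for: 240 trials
(60 per condition) in pseudo-random order with no condition repeated more
than 4 consecutive times, trial durations truncated-normal
7.26 ± 1.91 s (min 3 s), 5 s rest, 9 channels (FC3, FCz, FC4, C3, Cz, C4,
CP3, CPz, CP4) at 256 Hz.

**Trajectories.** Coupling is a convex morph of each hand's shape toward
the *other* hand's shape with weight `coupling/2` (at full coupling the
hands converge on the same average shape), plus a slow lateral wobble
(sum of 0.08–0.5 Hz sinusoids, 30 px SD) whose shared-across-hands
fraction grows with coupling, a 5% horizontal scale asymmetry of the
dominant hand (real drawings are never hand-symmetric, and without a
systematic asymmetry the curvature difference of congruent trials would
sit on the floor by coincidence alone), and 1 px white jitter. The circle
radius is 140 px: with the wobble's ~100 px contribution to extents this
reproduces the anchor values real participants produce (line-line extents
near 100 px — real lines are never perfectly straight — and circle-circle
extents near 380 px). Realized per-trial coupling is the condition's
nominal value (0.85 congruent, 0.45 incongruent) plus N(0, 0.12) noise,
clipped to [0.02, 0.98]. These choices reproduce the phenomena the
behavioural stage must detect: extent ordering line-line < incongruent <
circle-circle for both hands, and congruent mean CI (≈ 0.09) an order of
magnitude above incongruent mean CI (≈ 0.007).

**Latent drive.** The EEG encodes `d01`, the square root of the realized
CI rescaled to [0, 1] against the 98th-percentile reference (the square
root stabilises the reciprocal's heavy right tail; the quantile reference
stops a handful of near-floor trials from compressing everyone else's
dynamic range). `d01` correlates with raw CI at about 0.9, which caps how
well *any* readout of the EEG can correlate with CI.

**EEG.** Per channel: pink (1/f) background noise (10 µV SD, 30% of its
variance shared across channels, which keeps baseline coherence
non-degenerate), plus alpha (8–13 Hz) and beta (13–30 Hz) oscillations at
amplitude `snr` × the in-band background SD. Oscillation envelopes are
stabilised (the slow analytic envelope is divided out), modelling
sustained rhythms whose power is set by the applied gain rather than by
random envelope fluctuation; without this, envelope noise would swamp the
encodings at realistic gains.

Encoded gains are specified as the **measured** log10 band response the
downstream Morlet analysis should report, and converted to oscillation
gains by numerically inverting the per-channel response curve (wavelet-
weighted spectra of the generator's own components, co-modulated bands
counted as modulated power). This matters because the measured response
to an applied gain is convex — background power dilutes suppression more
than enhancement — and without the inversion a sign-balanced code would
leak a spurious *linear* correlation through its even part.

Encoding modes:

* `none` — no dependence; used for null calibration.
* `univariate` — C3-alpha response `0.8 × d01`. Expected ERD noise floor
  (driven mostly by the 1.5 s baseline window) is ~0.16 log units, giving
  a C3-alpha/CI correlation around 0.6–0.7 at snr 1.
* `distributed_linear` — a shared in-band source on all channels with
  strength `0.5 + 0.6 × d01`; raises band power and cross-channel
  coherence with the drive (the coherence stage's sensitivity case).
* `distributed_nonlinear` — twelve channel-bands (FC3/FC4, CP3/CP4,
  FCz/CPz × both bands) respond `0.5 ± 0.6 × d01`, the sign pattern fixed
  across channels but multiplied by a random per-trial sign. Each single
  channel-band is therefore uninformative in expectation (its
  distribution given the drive is sign-symmetric around the pedestal),
  while the rectified mean of the six signed pair differences recovers
  `d01` at r ≈ 0.9. The +0.5 pedestal exists because the suppression arm
  is physically capped near `log10(snr² + 1)` (silencing the oscillation
  entirely); riding the code on an enhancement pedestal lifts that cap
  and trebles the usable swing. The per-trial signs are drawn in matched
  pairs — trials ordered by drive × index product, opposite signs within
  consecutive pairs, the orientation of each pair a fair coin — which
  keeps every sign marginally random while cancelling, by construction
  rather than by luck, the finite-sample covariance between the signed
  code and the index (a covariance whose sampling scatter is inflated
  several-fold by the index's skew and would otherwise let single coded
  channel-bands exceed the familywise chance bound in a sizeable
  fraction of sessions).

## Spectral chain

0.5–35 Hz band-pass ("24 dB" read as 24 dB/octave, i.e. 4th-order
Butterworth, applied forward-backward for zero phase); optional
re-referencing to the mastoid mean (the generator emits already-referenced
data, so the default is a pass-through, and the ocular-ICA hook is an
identity for the same reason); epochs from −2 s to trial offset; Morlet
transform on 50 linearly spaced frequencies 1–35 Hz (the count is fixed,
the grid is a declared choice; linear spacing keeps band membership
unambiguous), 7 cycles at every frequency, Gaussian truncated at ±2 SD —
that truncation keeps the longest (1 Hz) wavelet shorter than the
shortest admissible epoch (3 s trial + 2 s pre-onset).

Baseline: per-frequency **geometric** mean power over −2000…−500 ms.
Since the map averages *log* ratios over time, the geometric-mean
baseline is the statistic that makes the map mean-zero when trial and
baseline power share one stationary distribution (an arithmetic-mean
baseline leaves a constant ≈ −0.25 Jensen offset in every cell — harmless
for correlations, but it breaks the "no modulation ⇒ ERD ≈ 0" self-test
and the sign convention that negative means suppression).

Variable-length trials are put on a common 200-point grid by linear
interpolation from onset to offset. Band membership on the frequency grid
is half-open `[lo, hi)` with the top band closed, so a point exactly at
13 Hz belongs to alpha only. The alternative band preset
(alpha 8–12, beta 15–30) is exposed as `default_bands("results-variant")`
because both definitions circulate for these motor bands.

ERD = mean of in-band cells over all 200 time points. The feature vector
keeps temporal dynamics: per channel and band, in-band frequencies are
averaged *at each time point*, giving 9 × 2 × 200 = 3600 values,
channel-major. By construction each ERD equals the time-mean of the
corresponding 200-point feature block, which the tests assert.

## Coherence

Welch magnitude-squared coherence: 1 s Hann windows, 50% overlap,
per-window mean removal, cross/auto spectra averaged over windows,
coherence averaged over in-band bins, then over the three pairs of each
channel group (frontal-central, central, central-parietal). Trials
shorter than two windows are excluded and reported. One estimation window
would give coherence identically 1, hence the hard two-window minimum.
The estimator's parameterisation (window, taper, overlap) is a declared
convention, fully exposed in the function arguments.

## The network and the split procedure

3600–100–1, tanh hidden, identity output, full-batch gradient descent on
MSE with momentum 0.9 and the variable-learning-rate rule: error down ⇒
lr ×1.05; error up by more than 4% ⇒ step rejected, lr ×0.7, momentum
flushed. lr starts at 0.01, at most 300 epochs. Early stopping: after 6
consecutive epochs without a new best validation error, training stops
and the best-validation parameters are returned. These are the
conventional constants of this training family; all are exposed.

Weight init is uniform ± `sqrt(6/(fan_in + fan_out))`. Hidden biases are
initialised uniform ±0.5 rather than zero: with zero biases every unit is
an odd function of its input, and the network starts blind to *even*
structure — exactly the structure the sign-balanced code lives in. Random
biases give the gradient purchase on that structure from epoch one; this
single choice is what separates reliable recovery from chance performance
on the nonlinear encoding.

Per iteration: a fresh random 85/5/10 split (204/12/24 trials of 240),
fresh init, input min-max scaling to [−1, 1] and target standardisation
fitted on the training portion only. The training target is the square
root of CI (variance stabilisation again: a few near-floor trials would
otherwise dominate the MSE); predictions are squared back to the CI scale
before anything is recorded, so all reported correlations are on raw CI.
Only test-set predictions are recorded — a trial's averaged prediction
never draws on an iteration that trained or validated on it, which the
tests verify from the logged test memberships. Coverage (≥ 5 test
appearances per trial) is enforced by extending the iteration budget; at
the reference 1000 iterations the binomial tail makes a violation
essentially impossible, at 50 iterations extension to roughly 150 is
expected and logged.

All randomness flows from one master seed through fixed per-stage
substreams, so every stage and the full pipeline are bit-reproducible.

## Evaluation

Pearson r with two-sided p from the t transform at n−2 df. Uncorrected p
values are reported (mirroring common practice for these exploratory
correlations) with a Bonferroni column added, α = 0.01. Zero-variance
features are reported as undefined rather than dropped. The cross-approach
comparison is descriptive — max |r|, significant counts, and whether the
network's r beats the best univariate |r| — plus a permutation null for
the **maximum** absolute correlation across all 24 univariate features
(the familywise chance level for "did any single feature correlate?").

## Problem sizes and runtime choices

The analysis scripts and the acceptance checks run the network stage at
50 requested iterations (extended as needed for coverage) rather than the
reference 1000; the mean test r stabilises well before 50 iterations on
the synthetic sessions, and the remaining Monte-Carlo error is reported
alongside. Test fixtures use 8–60-trial sessions for unit-level checks
and full 240-trial sessions for the recovery contrast.

## What passing does and does not show

The generator emulates condition structure, durations, interference
phenomenology, 1/f background, band rhythms and three encoding families.
It does not emulate ocular or muscle artifacts, electrode drift, volume
conduction, cross-frequency coupling, or nonstationary arousal, and its
rhythms are envelope-stabilised — cleaner than real ones. Passing the
recovery contrast therefore shows the *chain* is sound (no leakage, no
spurious univariate detection, real multivariate recovery), not that real
EEG carries such a code. On real recordings the attainable correlations
and the univariate/multivariate gap may differ substantially.

## Known limitations

* The response-curve calibration assumes the default analysis grid
  (50 frequencies, 7 cycles); analysing a generated session with very
  different Morlet parameters weakens the exact-null guarantee of the
  nonlinear encoding.
* The EEG interchange format is the package's text archive; binary
  clinical formats are out of scope.
* Incongruent-condition extent asymmetries seen in real data (each hand
  distorts differently) are not modelled — the morph is symmetric.
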