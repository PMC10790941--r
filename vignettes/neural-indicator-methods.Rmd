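---
title: "Methods: a subject-independent EEG indicator of task proficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a subject-independent EEG indicator of task proficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

During repeated-trial training (here: navigating to target rooms in a novel
environment, 60 trials in 10 blocks of 6), behavioral measures — completion
time, self-reported certainty — typically plateau before the underlying
neural reorganization does. A *passive* brain–computer interface that reads
proficiency from EEG could therefore tell a trainer something behavior
cannot: whether the trainee's neural activity has stabilized into the
"mastered" regime.

`nitrack` implements such an indicator. Two mental-state classes are defined
per participant from the certainty ranking of their trials: the bottom 10%
of trials are the *low-proficiency* state (class 0), the top 10% the
*high-proficiency* state (class 1). A linear SVM is trained on the labeled
1-second epochs of all *other* participants (leave-one-participant-out, so
the indicator is subject-independent by construction) and applied to every
epoch of the held-out session. The neural indicator of trial $t$ is

$$\mathrm{NI}_t = \frac{1}{n_t}\sum_{i=1}^{n_t} \bar c_i$$

with $\bar c_i$ the predicted class of epoch $i$ averaged over
classification runs and $n_t$ the trial's epoch count. Because the test set
is fixed across runs, averaging per-epoch over runs and then over epochs
equals averaging per-run NIs — the test suite asserts this commutation
exactly.

## Signal model of the synthetic cohorts

The human recordings behind this design are not redistributable, so the
package ships a generative stand-in whose statistical structure matches what
the analysis assumes. Every synthetic session contains, in order: one
eyes-closed 1-min baseline, then per block one eyes-open 1-min baseline
followed by six navigation trials, then a final eyes-closed baseline (the
`desk` preset scales these to 35 s and 4 blocks of 5; see below).

Each of the 64 channels carries:

* **1/f background noise** with slope $\beta \approx 1$ (per participant
  jittered by ±0.1), synthesized by an order-5 autoregressive approximation
  driven by a dedicated C++ random stream, scaled to 10 µV;
* a **theta tone** at IAF−5 Hz (4 µV × region weight);
* a **lower-alpha tone** at IAF−1 Hz (6 µV × region weight, constant);
* an **upper-alpha tone** whose amplitude is 6 µV × region weight × a
  per-trial gain. For responders the gain rises along the certainty
  trajectory from 1 to `alpha_effect_size` (default 2); for non-responders
  it stays at 1 ("flat") or falls to `1/alpha_effect_size` ("decreasing").

All tones are amplitude-modulated (25% depth, ~0.4 Hz) with random phases
per segment. Region weights are occipital 1.0, parietal 0.85, frontal 0.6,
temporal 0.35, central 0.3, log-normally jittered per participant — alpha is
occipitally dominant, and inter-participant variability (IAF drawn uniformly
from 8.5–12.5 Hz, jittered weights and slopes) keeps the subject-independent
classifier non-trivially challenged.

Two placement choices deserve a note. Eyes-closed baselines put their
(stronger, 18 µV) alpha tone **exactly at the IAF**, because that is what
IAF estimation must find. Task and eyes-open segments put the modulated tone
at **IAF+1 Hz — the center of the alpha-high band** — because a tone exactly
at the IAF sits on the boundary between the alpha-low2 and alpha-high bands
and would split its power between them, leaving no band cleanly carrying the
proficiency signal.

Behavioral trajectories are logistic saturations in trial index reaching
their plateau at the end of block 7 (block 3 of 4 in the desk preset):
certainty rises from ~2 to 10 (noise SD 0.8 ratings, added before integer
rounding and clipping to 1–10); the percent excess over each trial's ideal
time falls from 150% to 10% (noise SD 8%), capped at the 3-min trial limit
and floored at 5 s so every trial yields at least a few epochs. Responders
and non-responders share identical behavioral statistics — only the EEG
differs — mirroring the observation that behavioral convergence does not
separate the groups.

What the generator deliberately does **not** model: eye-blink/EMG artifacts,
electrode drift, re-referencing, event-related potentials, or any
within-trial task structure. Passing tests therefore show that the analysis
recovers a planted band-power effect under realistic noise and
inter-participant variability — not that it survives real-world artifact
contamination (the preprocessing exposes an `artifact_hook` where a real
deployment would plug ICA or regression cleaning).

## Preprocessing

The fixed order is: resample 500→256 Hz → band-pass 1–50 Hz → (hook) → IAF →
band definitions → filter–Hilbert power → baseline z-scoring.

All filters are **zero-phase spectral masks** with raised-cosine transitions
of 0.5 Hz. Sessions are zero-padded to a whole, 2-3-5-smooth number of
seconds, which makes the 500 Hz and 256 Hz DFT grids share bin spacing, so
resampling is an exact spectral truncation (an ideal anti-alias filter) and
the 64/125 length ratio is exact. `preprocess_session()` fuses these steps
around one forward FFT; the tests verify the fused path agrees with the
composed standalone operations to ~1e-5 away from the padded session edges
(the two paths treat the pad region differently, which matters only within a
filter-length of the session boundaries — no analysis window sits there).

* **IAF**: Welch periodogram (4 s Hann windows, 50% overlap → 0.25 Hz grid)
  averaged over O1/Oz/O2 (configurable), argmax in 8–15 Hz, averaged over
  the two eyes-closed baselines to absorb slow drift. A flat spectrum (peak
  < 2× the in-band median) raises a no-peak error; callers may fall back to
  a configured default of 10 Hz.
* **Bands**: theta `[IAF−6, IAF−4]`, alpha-low1 `[IAF−4, IAF−2]`, alpha-low2
  `[IAF−2, IAF]`, alpha-high `[IAF, IAF+2]` — four contiguous 2 Hz bands.
* **Power**: squared magnitude of the analytic signal (band-masked positive
  frequencies doubled). The squared-envelope convention cancels in the
  z-scores, so no constant factor matters downstream.
* **Normalization**: per channel and band, subtract the mean and divide by
  the SD of the first eyes-open baseline segment; the baseline itself is
  then standardized to 1e-9 exactness (asserted).
* **Segment remapping** under resampling uses floor for starts and ceiling
  for ends, so no segment sample is lost; adjacent segments may share one
  boundary sample, which is immaterial because epochs are cut from segment
  starts.

## Features, labels, classification

Features are epoch means of z-scored power: 41 montage channels (central
strip, reference FCz and ground FPz excluded; the exact membership is an
editable CSV) × 4 bands = 164 columns; trailing partial seconds of a trial
are discarded. Trials are ranked by ascending certainty with completion
order breaking ties — one stable sort, so the labeling is invariant to row
order. With $n$ trials the per-class count is $\lfloor 0.1 n \rfloor$
(minimum 2).

Per LOPO run: every training participant's larger class is subsampled
(never upsampled) to the smaller class's count; mRMR (MID criterion,
mutual information on 3-level equal-frequency discretized features, ties to
the lowest column index) picks $k = 10$ features; features are standardized
by training statistics; a linear SVM with $C = 1$ is fit (training is
balanced, so no class weights); every epoch of the held-out participant is
predicted. 100 runs average out the subsampling noise; the test data never
change across runs, and a dedicated test perturbs the held-out data to
assert that neither the selected features nor the decision function move.

The **permutation null** shuffles class labels within each training
participant (label counts preserved), reruns the identical
balance–select–train–predict procedure, and scores the accuracy on the
session's extreme blocks (first-block epochs correct when predicted 0,
last-block when predicted 1). With 1 run per permutation (vs 100 for the
true statistic) the null's location is unbiased while the cost stays
desk-tractable; `n_runs_null` raises it when wanted. The p-value is the
proportion of null accuracies ≥ the true accuracy; a participant is graded
"NI-effective" when p beats `max(alpha, 1/n_perm)`.

## Statistics

* **Block NI** is the *unweighted* mean of trial NIs within a block
  (epoch-weighted available via `epoch_weighted = TRUE`).
* **Trend**: `ni_block ~ block + (1 | participant)` via REML. The default
  p-value uses the normal approximation to the t statistic (df reported as
  $n - 2$ nominally); Satterthwaite via lmerTest is available through
  `df_method = "satterthwaite"`. A singular fit (no between-participant
  variance, e.g. noiseless test data) falls back to OLS with
  participant-clustered robust standard errors and is flagged in the result.
  Random slopes were considered and rejected: with ≤ 10 blocks per
  participant the random-slope model is weakly identified and frequently
  singular, and the question asked of the model is about the mean trend.
* **Correlations**: per participant, Pearson r of trial NI against certainty
  and against percent time performance, over all trials and over the first
  plus last 20% of trials ("extremes"), where a two-state classifier is most
  interpretable (mid-session the indicator interpolates between states and
  is intentionally not treated as an absolute scale).
* **Per-trial confidence bands** (plots) are normal-approximation 95%
  intervals across runs — across-run spread is the quantity the 100-run
  design controls, whereas across-epoch spread mixes within-trial dynamics
  into the uncertainty.
* **Feature histograms** count selections over runs; totals are conserved at
  exactly $k \times$ runs $\times$ participants.

## Problem sizes, presets, determinism

Two presets: `paper` mirrors the study geometry (15 participants, 60 trials
in 10 blocks, 1-min baselines, 100 runs, 1000 permutations) and is
hours-scale; `desk` (6 participants, 20 trials in 4 blocks of 5, 35 s
baselines, 30 s trial cap, ideal times 8–15 s, 10 runs, 50 permutations) is
what the test suite and the acceptance script use — small enough to iterate
with, large enough that every stage is exercised with hundreds of epochs per
participant. The desk block size is 5 because the trial count must divide
into whole blocks; its plateau block is 3 of 4, proportional to 7 of 10.

Every random draw — participant parameters, trajectories, noise, balancing
subsamples, permutations — derives from one master seed through per-context
streams (participant × run × permutation), so results are reproducible and
independent of evaluation order; cohort generation is byte-identical across
reruns, and `run_pipeline()` writes a manifest keyed by a hash of the full
configuration, skipping completed stages on resume.

## Known limitations

* The synthetic effect is a single narrow-band amplitude gain; real
  proficiency signatures are likely broader-band and less stationary.
* The block-extremes accuracy is epoch-weighted, and early trials are
  longer than late ones, so first-block epochs dominate the denominator. A
  degenerate predictor that calls *every* epoch "low proficiency" therefore
  scores the first-block epoch share (~0.7 under the default trajectories)
  rather than 0.5, and in a mixed cohort a flat non-responder — whose
  epochs genuinely all resemble the low state — can beat the (correctly
  0.5-centered) permutation null. In fully zero-effect cohorts the held-out
  accuracy sits at chance and the test is calibrated, as the suite asserts;
  for grading synthetic non-responders, the block-trend test is the sharper
  instrument.
* The EDF writer/reader is minimal (16-bit, uniform rate, no annotations
  records); segmentation travels in the sessions CSV instead.
* The permutation scope shuffles *training* labels; the held-out scoring is
  fixed by block membership. Other reasonable scopes (e.g. shuffling test
  blocks) would answer slightly different null hypotheses.
* Mid-session NI values interpolate between two trained states and should
  be read as trends, not calibrated proficiency probabilities.
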