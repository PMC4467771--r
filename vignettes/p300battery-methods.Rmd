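---
title: "Methods: a P300b-based cognitive assessment battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a P300b-based cognitive assessment battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Motivation and scope

Patients with severe motor impairment — most acutely, disorders of
consciousness — cannot be assessed with standard neuropsychological tests,
which all assume a motor or verbal response channel. The P300b event-related
potential offers a motor-independent readout: it is a positive deflection,
maximal over centro-parietal scalp around 300–600 ms, elicited by rare,
attended, task-relevant stimuli. If a listener covertly counts a designated
word inside a stream of equiprobable spoken words, the counted word's epochs
carry a P300b and the others do not; which word was attended can therefore be
decoded from EEG alone.

`p300battery` implements a complete assessment pipeline around this idea:

1. **Protocol generation** for three auditory tasks — attention/command
   following (AT), a Sternberg-style working-memory span task (WM), and a
   grammatical reasoning task (AR);
2. **Forward simulation** of a participant (behavioral agent plus 16-channel
   EEG), so every stage is testable without recordings;
3. **Preprocessing** (band-pass, epoching, baseline correction, artifact
   rejection);
4. **Condition binning** implementing each task's correct/incorrect logic;
5. **Cluster-mass permutation tests** (CMPT) at group and single-participant
   level;
6. **Normalized-magnitude (NM) modelling** of individual performance;
7. A **Monte Carlo analysis** of how statistical sensitivity scales with
   testing time and accuracy.

## The battery protocol

Eight monosyllabic nouns (ids 0–7) form the vocabulary. A *stream* plays each
word exactly *r* times, *r* ∈ {7, 8, 9, 10}, in shuffled order — 56–80 words
per trial, 400 ms per word with a 100 ms gap (one 500 ms slot). A session is
six blocks of 12 trials, ordered AT, WM, AR, AT, WM, AR:

* **AT**: the experimenter names a target; the participant counts it.
  Each word is target exactly 3 times over the 24 trials.
* **WM**: a memory set of 4, 6 or 8 words is presented (each size in exactly
  8 trials), then "what was the *x*th word?"; the participant counts their
  answer in the subsequent stream.
* **AR**: a sentence such as "cake is not followed by dot" names two words;
  the participant counts the word in first temporal position. The 24
  sentences are unique, three for each of the 2×2×2 templates
  (precede/follow × active/passive × positive/negative). The solver uses the
  parity rule: the first-mentioned noun is the answer exactly when an even
  number of the three inversions (follow, passive, negative) apply. This
  reproduces the task's published truth table (asserted in the test suite).

Timing arithmetic: one attended target occupies one slot and comes with
seven distractor slots, hence 4 s of stream per target; 75 targets ≈ 5 min.
Chance level with 8 words is 12.5%.

Where the protocol leaves choices open we fixed them once: *r* is balanced
within block (each value 3× per 12 trials); WM memory sets are drawn without
replacement; AR noun pairs are drawn without replacement and sentence
uniqueness is enforced on (noun1, noun2, template); immediate word repeats
are allowed by default (a config flag forbids them). All randomness flows
from one integer seed.

## The synthetic participant

`simConfig()` fixes the generative model:

* **P300b kernel**: a single raised-cosine half-wave, peak 4 μV at 450 ms,
  full width 400 ms, added at the onset of every stream word that matches the
  word the agent attends. Unattended words add nothing. Multi-component
  morphology (N1/P2) is deliberately not modelled: the inference targets only
  the attended-vs-unattended difference, which this captures.
* **Topography**: weight 1.0 at CPZ/PZ/POZ, 0.6 at CP3/CP4/OZ, 0.3 elsewhere
  — posterior-maximal; the exact values are free parameters.
* **Noise**: per-channel AR(1) with coefficient 0.95 scaled to a stationary
  SD of `noiseSD` μV (default 9), approximating low-frequency-dominated EEG;
  white and 1/f ("pink") modes exist for oracle tests. Channels are
  independent — real EEG noise is spatially correlated, so real region
  averaging gains less than the simulation suggests.
* **Behavioral agent**: attends the word it answers. WM answers are correct
  with a set-size-specific probability (defaults 0.97/0.80/0.64, the healthy
  range), otherwise a uniformly wrong set member; AR answers are correct with
  probability 0.95, otherwise the other noun; count reports are correct with
  probability 0.70, otherwise off by one within the offered options 7–10.

The default `noiseSD = 9` is a calibration, not a measurement: no SNR is
published for this paradigm, so the default was chosen (once) such that the
Monte Carlo analysis at accuracy 1.0 first reaches mean p < 0.05 between 50
and 100 attended targets, bracketing the ~75 the method reports in healthy
listeners. The inter-stream gap in synthesized recordings defaults to 1 s —
the protocol's 10 s rests carry no analyzable EEG, and the gap does not
enter any statistic; `timingModel()` keeps the protocol's true constants for
duration arithmetic.

What passing tests on this generator do **not** show about real data:
robustness to eye/muscle artifacts (only amplitude outliers are simulated),
to spatially correlated noise, to latency/amplitude variability across
trials and participants, or to drifting electrode impedances.

## Preprocessing

* **Filtering**: 0.5–10 Hz, 4th-order Butterworth high- and low-pass applied
  with zero phase. The realization is frequency-domain multiplication by the
  cascade's squared magnitude response (the filtfilt equivalent), on an FFT
  length padded to the next 2-3-5-composite; zero phase preserves P300
  latency.
* **Epoching**: −200 to 1000 ms around each word onset; window sample
  indices are `floor(onset*fs) + (round(-0.2*fs) : round(1.0*fs))`, both
  ends inclusive — 308 samples at 256 Hz. Events whose window leaves the
  recording are dropped with a warning.
* **Baseline**: per channel and epoch, the mean over samples with t < 0 is
  subtracted (a projection: idempotent by construction).
* **Artifact rejection** operates at the epoch level with the statistics
  published for component screening (kurtosis |z| > 5, absolute amplitude >
  100 μV, joint-improbability |z| > 5, linear trend with R² > 0.5 and fitted
  range > 75 μV); ICA itself is out of scope, so the same statistics are
  applied to epochs — a disclosed deviation. Rejection precedes binning so
  both conditions face identical criteria. Thresholds are global, not
  per participant.

## Condition binning

* **AT**: positive = target-word epochs; negative = the 7 other words
  (1:7 in expectation).
* **WM**: positive = epochs of the *correct* word regardless of the answer
  given; negative = all other words. At chance performance the P300b falls
  equally often in both bins and the contrast nulls out — this is what makes
  the test specific to correct performance.
* **AR**: positive = the correct noun's epochs, negative = the *other
  sentence noun only*; the remaining six words are excluded rather than
  pooled. Pooling them would dilute the incorrect bin: a participant who
  solves the sentence wrongly still attends one of the two nouns, and six
  flat ERPs would mask that P300b, biasing the contrast toward false
  positives.
* **Behavioral binning** (for the Monte Carlo): attended = epochs matching
  the participant's answer, right or wrong.

Single-participant analyses pool epochs across a task's trials and compare
the two pooled sets; the per-target-word alternative is not modelled (the
pooled reading is the one adopted and flagged as an interpretation).

## Cluster-mass permutation test

Pointwise t statistics (paired over participants at group level, df = n−1;
pooled-variance two-sample over epochs at single level, unbalanced groups
allowed) are thresholded at the two-sided point-level critical t
(`clusterAlpha` = 0.05 at the relevant df). Supra-threshold points of each
sign are grouped into connected components — same electrode at adjacent
samples, or neighboring electrodes at the same sample — and scored by summed
t (*mass*). The null of the maximum |mass| is built from 1000 sign flips of
participant difference maps (group) or 500 re-partitions of the pooled
epochs into the original group sizes (single); p = (exceedances + 1) /
(nPerm + 1), so p > 0 always. For ≤ ~10 pooled epochs an exact mode
enumerates all partitions instead. Electrode adjacency uses projected 10-10
coordinates (head disc of radius 0.5, topographic-plot convention) with a
0.4 neighbor threshold; clustering is restricted to 0–1000 ms (baseline
samples excluded). Ties in |mass| break toward the earliest-onset cluster.
Degenerate zero-variance points score a saturated t (±1e9) when the means
differ and 0 otherwise, so constant shifts cluster correctly instead of
vanishing.

The detail-level choices (threshold, sidedness, permutation count) are
assumptions exposed as configuration, since no authoritative specification
of them is available for this paradigm.

## Normalized magnitude and individual differences

If a participant performs at accuracy *a*, a fraction *a* of correct-word
epochs are also attended; the rest average to zero. The correct-condition
magnitude should therefore be the attended-condition magnitude times *a*
(4 μV attended at 75% → 3 μV), and the **normalized magnitude** NM =
correct/attended estimates *a* directly. NM is computed per WM set size over
the spatiotemporal region selected by the group-level AT CMPT (the only
region guaranteed to exist for every participant; per-participant regions
are a config option), giving 3 records per participant. Records with
non-positive attended magnitude are excluded — the ratio is unstable there.

The performance model is a binomial GLM (logit link, 8 trials per cell):
performance ~ set size (factor) + NM + interaction, with sequential
likelihood-ratio chi-squares per term; a Gaussian identity-link fit is
available for comparison since the original analysis's family is not
specified. Pearson correlations between NM and performance are provided per
set size; ceiling performance (zero variance) raises an explicit error
rather than returning an undefined r.

NM is a ratio of noisy region means, so single records (8 WM trials per set
size) are noisy and slightly biased upward by denominator noise; recovery of
the
identity relationship is therefore assessed on NM averaged across seeds and
set sizes in the test suite, and the raw per-record correlation is printed
alongside.

## Monte Carlo sensitivity analysis

For one participant: pool attended/unattended epochs by behavioral answer;
for each target count *n* (multiples of 25) draw *n* attended and 7*n*
unattended epochs (without replacement while the pool lasts, with
replacement — flagged — beyond it, as required for *n* up to 600 from a
~600-epoch session); to simulate accuracy *a*, exchange round((1−a)·n)
members between the conditions; run the single-level CMPT (500 permutations
by default; 200 in the scaled test suite); repeat (100 times by default, 20
in the suite) and average the p-values arithmetically. `requiredTargets()`
returns the first grid *n* whose mean p drops below α. At the chance
accuracy 0.125 the swapped conditions have identical P300b composition, so
the procedure is null by construction — the mean p stays high at every *n*.
Curves are computed per participant; averaging across participants is done
by the caller.

## Problem sizes in the test suite

The suite's statistical checks use: 200 null simulations at 500 permutations
(16 ch × 308 samples, 24 vs 168 epochs) for type-I calibration; 10 seeds ×
14 participants (AT + WM blocks, i.e. every trial the NM analysis consumes)
for parameter recovery; Monte Carlo grids to n = 600 at 20 repetitions and
200 permutations for the chance-level null and to n = 225 for the accuracy
ordering. These sizes keep the full suite in the tens of minutes on one core
while leaving every assertion's tolerance untouched.

## Known limitations

* The generator's noise is spatially white across channels and stationary;
  real EEG is neither.
* Epoch windows overlap the following two stimulus slots, so kernel energy
  bleeds between neighboring epochs; this is physiologically realistic
  (real ERPs overlap too) but means "unattended" epochs adjacent to attended
  ones are not strictly flat.
* ICA-based artifact removal and re-referencing are out of scope; the
  rejection stage screens epochs only.
* The behavioral count report is modelled as performance bookkeeping and
  does not modulate the EEG.
* Group-level inference assumes the 14-participant paired design; no
  between-group comparisons are implemented.
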