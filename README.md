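# p300battery

Motor-independent cognitive assessment from EEG alone. `p300battery`
implements an auditory P300b assessment battery: a participant listens to
streams of eight spoken words and covertly counts one of them, and the
P300b — a positive event-related potential over centro-parietal scalp,
peaking ~450 ms after rare attended stimuli — reveals which word was
counted. Because answering requires no movement, the battery targets
populations that behavioral neuropsychology cannot reach: disorders of
consciousness, locked-in syndrome, severe motor impairment.

The package is aimed at EEG methodologists and clinical neuroscience groups
who want to generate the protocol, validate the analysis chain on simulated
recordings, or run the statistics on their own data.

## What it implements

**Three tasks.** Auditory attention (AT: count an experimenter-given
target), working memory (WM: Sternberg-style span task — recall the *x*th
word of a 4/6/8-word set, then count it), and auditory reasoning (AR: solve
"cake is not followed by dot" for the word in first position, then count
it). A session is 6 blocks × 12 trials with exact counterbalancing (each
word an AT target 3×, each WM set size 8×, each of the 8 sentence templates
3×).

**Inference.** Epochs (−200–1000 ms, 0.5–10 Hz zero-phase band-pass,
baseline-corrected, artifact-screened) are binned into condition pairs —
attended vs unattended (AT), correct vs incorrect word (WM), correct noun vs
the other sentence noun (AR) — and compared with a spatiotemporal
cluster-mass permutation test (CMPT): pointwise t maps thresholded at the
two-sided point-level critical t, supra-threshold points joined over
electrode adjacency × temporal contiguity, clusters scored by summed t, and
the largest |mass| referred to a permutation null (sign flips of participant
difference ERPs at group level; re-partitions of pooled epochs at
single-participant level),

    p = (#{null max |mass| >= observed} + 1) / (n_perm + 1).

**Individual differences.** A participant at accuracy *a* attends the
correct word in a fraction *a* of trials, so the correct-condition magnitude
is the attended-condition magnitude × *a*; the normalized magnitude
NM = correct/attended (over the CMPT-selected region) estimates *a*. A
binomial GLM relates performance to set size and NM.

**Sensitivity.** A Monte Carlo procedure subsamples *n* attended + 7*n*
unattended epochs, swaps a fraction 1−*a* between conditions to simulate
accuracy *a*, and averages single-level CMPT p-values over repetitions —
yielding mean p as a function of testing time (4 s of stream per attended
target) and accuracy.

**Simulation.** A built-in generator produces a behavioral agent with
configurable per-task accuracy and 16-channel, 256 Hz EEG (posterior-maximal
4 μV raised-cosine P300b at attended onsets, AR(1) noise), plus EDF and TSV
I/O, so the whole chain runs and is tested end-to-end without any real
recording.

## Worked example

```r
library(p300battery)

sched <- buildSchedule(seed = 1)          # 72-trial session plan
cfg   <- simConfig(noiseSD = 9)           # default synthetic participant
set.seed(1)
agent <- simulateAgent(sched, cfg)        # behavioral responses per trial
rec   <- synthesizeRecording(sched, agent, cfg)   # continuous 16-ch EEG
rec   <- bandpassFilter(rec)                      # 0.5-10 Hz zero-phase
ep    <- baselineCorrect(epochRecording(rec))     # -200..1000 ms epochs

b   <- binSession(ep, sched, "AT")        # attended vs unattended epochs
res <- cmptSingle(ep, b$positive, b$negative, nPerm = 500)
res
```

```
CMPTResult (single level): 8 cluster(s), overall p = 0.001996
  largest: mass 1754.8 (+), 508 points, 320-648 ms, p = 0.001996
  threshold |t| > 1.961, 500 permutations
```

The attended-word P300b appears as a large positive cluster over the
posterior channels around 320–650 ms; p ≈ 0.002 is the permutation floor at
500 permutations (1/501), i.e. no null re-partition produced a comparable
cluster mass, so this simulated participant's command following is detected
decisively. The same call on `binSession(ep, sched, "WM")` or `"AR"` tests
correct task performance, and

```r
predictedCorrectMagnitude(4, 0.75)   # 3: expected correct-condition uV
```

shows the linear performance-scaling model behind the NM analysis.

A thin CLI over the same functions lives at `inst/cli/battery.R`
(`schedule`, `simulate`, `run` subcommands).

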