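---
title: "Decoding tactile attention from somatosensory ERPs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding tactile attention from somatosensory ERPs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpbci)
```

## The decoding problem

An electrotactile brain-computer interface delivers brief electrical pulses
alternately to two nearby sites on the user's right forearm — D over the
extensor carpi radialis (a radial-nerve branch) and V over the flexor carpi
radialis longus (a median-nerve branch) — while the user covertly attends
one of the two sites. Both sites are stimulated with *equal* probability,
so, unlike oddball P300 designs, any difference between the conditions is
created purely by selective tactile attention: attending a site increases
the amplitude of the somatosensory event-related potential (sERP) its
stimuli evoke. The decoder's task is binary: from a short stretch of
single-channel EEG, decide which site the user is attending (class AD =
attending D, class AV = attending V).

`serpbci` implements the complete decoding chain and, because no public
recording of this paradigm exists, a synthetic-EEG generator that emulates
the experiment closely enough to exercise and validate every stage.

## The stimulation protocol

A session consists of `n_blocks = 6` blocks of 300 stimuli. The attended
location alternates between blocks (starting side drawn from the seed).
Each block is divided into 5 sub-blocks of 60 stimuli, in which each site
receives a pseudo-random count between 25 and 35; the per-sub-block counts
are drawn so that every block delivers exactly 150 stimuli per site, which
makes the session total 1,800 stimuli, 900 per site. Within a sub-block,
stimulus order is a shuffled multiset rejected and redrawn until no more
than 3 consecutive stimuli hit the same site; the run constraint is
enforced across sub-block boundaries as well, which is slightly stricter
than required. Stimuli are spaced by the 700 ms inter-pulse interval
(840 samples at 1,200 Hz); sub-blocks are separated by 10 s pauses in
which the subject reports the counted stimuli. The first stimulus sits
after a 2 s warm-up so that the first epoch's baseline exists.

`generate_schedule()` produces the event table; `validate_schedule()`
re-checks every invariant by exhaustive scan and never throws, so it can
audit externally supplied event tables too.

## The synthetic subject

`subject_model()` describes one synthetic subject:

* **SEP templates.** Per-site single-trial responses are sums of
  Gaussian-windowed component lobes with the canonical P1/N1/P3 morphology.
  The published waveforms of this paradigm are not machine-readable, so the
  amplitudes are conventions, chosen once at realistic scalp magnitudes:
  P1 +2 µV at 50 ms (sd 15 ms), N1 −4 µV at 120 ms (sd 25 ms), P3 +3 µV at
  280 ms (sd 60 ms) for site D; site V is slightly smaller and ~5 ms later
  (+1.6/−3.4/+2.5 µV), reflecting that a different nerve territory
  projects slightly differently. A per-channel gain map (C3 = CP3 = 1.0,
  Cz = 0.8, Pz = 0.6, C4 = 0.4, Fp1 = 0) encodes contralateral dominance
  for right-forearm stimulation.
* **Attention effect.** A multiplicative gain (`attention_gain`, default
  1.5) scales the whole template of whichever site is currently attended —
  the generator's rendering of the observed overall amplitude increase for
  attended stimuli. Gain 1 makes the two classes exchangeable and is the
  null configuration used for calibration.
* **Background noise.** 1/f ("pink", `pink_exponent = 1`) Gaussian noise,
  `noise_sd_uV = 10` by default. The level was calibrated once so that
  single-channel SEP3 decoding at gain 1.5 sits mid-range between chance
  and ceiling — the regime in which the averaging effect is measurable;
  at 20 µV the whole operating range collapses toward chance. Mains
  interference is omitted: the acquisition amplifier notch-filters 50 Hz.
* **Blinks.** Poisson-timed (0.1 Hz) raised-cosine deflections of 300 ms,
  120 µV on Fp1 with fixed fractional projection onto the scalp channels
  (0.08–0.20). They exist to exercise the EOG rejection rule.

What the generator does **not** emulate: biophysical volume conduction,
habituation/adaptation over the session, non-stationary alpha bursts,
electrode drift or motion artifacts, and any single-trial latency jitter.
Passing tests on this generator therefore demonstrate the correctness and
leakage-freeness of the *pipeline*, not expected accuracy on human EEG.

## Preprocessing

The front end follows ERP convention: 2nd-order Butterworth bandpass
0.1–25 Hz (zero-phase by default — the offline standard; a causal flag
exists for pseudo-online replay), segmentation into 500 ms epochs
(half-open window `[onset − 120, onset + 480)` samples, i.e. 100 ms
baseline + 400 ms post-stimulus; the stimulus sample belongs to the post
window), per-channel baseline-mean subtraction, and dual-threshold
artifact rejection over the full epoch: strictly above 50 µV absolute on
any scalp channel (reason "EEG") or above 80 µV on Fp1 (reason "EOG").
Boundary-equal values are kept, since only *crossing* a threshold rejects.
The 50 µV rule is applied to scalp channels only; Fp1 is governed solely
by its 80 µV rule.

## sERP averaging and difference waves

Kept epochs are partitioned by (attended site, stimulated site) into the
four clusters ADSD, ADSV, AVSD, AVSV — a full artifact-free session gives
450 trials per cluster. For an averaging depth `n_avg` ∈ {3, 5, 10}
(SEP3/SEP5/SEP10), each cluster is truncated *from the end* to the common
group count m = min(floor(size / n_avg)) × n_avg and split into m
consecutive, non-overlapping groups in acquisition order; consecutive
grouping (not sliding windows) preserves pseudo-online semantics and the
450 → 45 SEP10 arithmetic. Group averages use the 480-sample post-stimulus
window and are decimated by 8 (every 8th sample starting at the first
post-stimulus sample) to 60 samples at an equivalent 150 Hz — plain
decimation is safe because the 25 Hz low-pass leaves negligible energy
above the new 75 Hz Nyquist; block-averaging is available as an option.

Difference waves subtract the V-stimulation sERP from the D-stimulation
sERP within a condition — diffsERP(AD) = sERP(ADSD) − sERP(ADSV),
diffsERP(AV) = sERP(AVSD) − sERP(AVSV) — and the between-condition
selection wave is diffsERP(ADAV) = mean diffsERP(AD) − mean diffsERP(AV).
Per-group (not condition-mean) difference waves are used as F2 examples,
because cross-validation needs many examples; the condition means enter
only the ADAV selection wave.

## Features and threshold selection

* **F1**: the i-th pair of averaged, downsampled sERPs of a class joined
  into one 120-sample vector, D-stimulation samples first.
* **F2**: the i-th within-condition difference wave, 60 samples.
* **FS1/FS2**: an amplitude threshold sweeps 0, 0.1, 0.2, … µV over the
  rectified diffsERP(ADAV); at each threshold the sample indexes at or
  above it are kept (index sets are nested and shrink monotonically), and
  the sweep stops before the first empty set. FS1 keeps the selected
  indexes of both sERPs of the pair (2 × |indexes| features), FS2 the
  selected indexes of the difference wave.

The final threshold choice is not prescribed by the protocol, so the
package makes it explicit and leakage-free: by default an inner
leave-one-out pass over the *training fold* scores every threshold in the
sweep and the smallest threshold attaining maximal inner accuracy wins
(ties therefore resolve toward more features). A fixed numeric threshold
can be supplied instead; a fixed threshold whose selection is empty falls
back to threshold 0, which reproduces F1/F2 exactly, so the classifier
always receives at least one feature.

## Classification and cross-validation

Two classifiers are supported: an RBF-kernel SVM (kernel
exp(−‖u−v‖²/σ²), σ from the median pairwise Euclidean distance of a
seeded subsample of the training examples, box constraint 1) and
rank-reduced (SVD-semantics) LDA, appropriate when features outnumber
examples. An SVM decision value of exactly 0 predicts AD (fixed,
documented tie rule).

The leave-one-out unit is one averaged-group example. In every fold, the
ADAV selection wave, the threshold choice, and the kernel-scale heuristic
are recomputed from the training fold only, so the held-out example can
never influence its own feature set or model — the property the leakage
audit test asserts by mutating the held-out example and checking the
training-side artifacts are bit-identical. A deliberately leaky
`fs_mode = "pooled"` (selection computed once from all examples) exists
for sensitivity analysis. The protocol description of per-iteration
fine-tuning is ambiguous about the selection scope; a literal test-set
reading is ill-defined for a single held-out example (ADAV needs both
classes), so the training-fold reading — the one consistent with the
stated train/test independence — is the default.

**Equal class priors.** Leave-one-out training folds are imbalanced by
exactly one example: the held-out class is always the training minority.
A prior-sensitive classifier then systematically anti-predicts the
held-out class, biasing the chance level far below 50 % (we measured
~26 % pooled null accuracy for the unweighted SVM). Because the paradigm
delivers both classes with equal probability, both classifiers train
under equal priors — balanced per-class SVM weights and uniform LDA
priors (`classifier_spec(balanced = )`). This restores the null to ~50 %
and is the package's own design decision.

Accuracy is the percentage of correct folds; `confusion_table()` reports
the 2×2 matrix in percent of all folds (TP(D), FP(D); FP(V), TP(V)),
whose trace equals the accuracy.

## Evaluation harness

`decision_time()` gives n_avg × ISI × 2 locations = 4.2 / 7 / 14 s for
SEP3/5/10. `itr_bpm()` computes Wolpaw bits per decision,
B = log₂N + P log₂P + (1−P) log₂((1−P)/(N−1)), scaled by 60/T; the
two-target perfect-accuracy limits are 14.29, 8.57 and 4.29 bits/min.

`rm_anova()` runs one- or two-way repeated-measures ANOVA (classifier ×
averaging depth, or the four feature methods) with classical
sums-of-squares partitioning and Greenhouse–Geisser correction for
factors with more than 2 levels (both corrected and uncorrected df are
reported); effects with zero between-condition variance are reported as
F = 0. `wilcoxon_posthoc()` applies the paired signed-rank test with
Bonferroni thresholds α/m (0.017 for 3 comparisons, 0.0083 for 6); zeros
are handled by the Pratt method (zeros are ranked, their ranks discarded
from the statistic) with a normal approximation, while the exact
distribution is used when there are no zeros or ties — the variant choice
is documented here because the original analysis does not state one.

## Numerical choices and degenerate inputs

* Threshold comparisons in artifact rejection are strict (`>`); selection
  thresholds are inclusive (`>=`), matching "equal or exceed".
* The threshold grid is built as k × increment (not cumulative addition)
  to avoid floating-point drift.
* The ADAV wave of an all-zero dataset admits only threshold 0, selecting
  all 60 indexes — the FS methods then equal F1/F2 by construction.
* `kernel_scale_heuristic()` errors on coincident points (median distance
  0); `train_classifier()` refuses single-class folds and non-finite
  features; `balance_and_group()` names the cluster that is too small.
* All randomness flows through explicit integer seeds (`with_seed`
  restores the caller's RNG state); equal seeds give byte-identical
  schedules, recordings and results.

## Validation design and problem sizes

The packaged test-suite checks run at sizes chosen to make each property
measurable: protocol arithmetic on the full 6-block default session; exact
algebraic identities (template reconstruction, gain scaling, the
(g−1)(D+V) difference-wave identity) on noise-free 2-block sessions;
null calibration on ten 4-block gain-1 sessions of 200 SEP3 examples
each, whose pooled accuracy is compared with the binomial 95 % interval
around 50 % for n = 200 (per-dataset leave-one-out estimates from much
smaller runs are overdispersed relative to binomial, an artifact of tiny
correlated fold sets rather than of the pipeline); and the averaging
effect on ten 2-block, 240-stimulus sessions at gain 1.5, where the
median accuracy over seeds must be non-decreasing from SEP3 through
SEP10, mirroring the signal-to-noise argument for single-trial averaging.

## Known limitations

* The generator's attention effect is a pure template gain; real
  attentional modulation can be component-specific and latency-shifting.
  A per-component additive mode would be a natural extension.
* 1/f noise is stationary across the session; consecutive-trial averages
  therefore decorrelate slightly faster than in drifting real EEG.
* Accuracies obtained on synthetic subjects are not predictions of human
  performance; only the structural results (arithmetic, geometry, ITR,
  null behavior, ordering of averaging depths) are meaningful claims.
* EDF and HDF5 interchange are not provided; recordings, events, epochs
  and results travel as delimited text and JSON.
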