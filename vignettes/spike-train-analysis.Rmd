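---
title: "Analysing cached- and inferred-value prediction errors in VTA spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing cached- and inferred-value prediction errors in VTA spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtarpe)
```

## The scientific question

Phasic firing of midbrain dopamine neurons is classically described as a
temporal-difference (TD) reward prediction error: the difference between the
reward-plus-discounted-value that actually arrives and the value that was
cached on the current stimulus through its own pairing history with reward.
A purely model-free account makes a sharp prediction in sensory
preconditioning. If cue A is first paired only with another neutral cue B
(A then B, no reward), and B is later conditioned with reward while A is
never presented, then A can carry no cached value; its onset should elicit
no dopaminergic prediction error at a probe test, even though animals
respond to A behaviourally. A model-based learner, by contrast, can chain
the learned A-to-B transition with B's learned reward and assign A an
*inferred* value at probe.

`vtarpe` packages the analysis pipeline needed to ask this question of
trial-aligned VTA spike trains: the bin-wise ROC normalization of firing
rates, the response-dynamics classification that isolates putative dopamine
neurons, the population statistics that contrast cached (B minus D) and
inferred (A minus C) value coding, agent simulations that formalize the
model-free/model-based dissociation, and a synthetic-data generator that
makes every stage testable without access to recordings.

## Task structure

The task has three phases, encoded in `task_spec()`:

1. **Preconditioning** (2 sessions x 12 trials): two pairs of 10-s auditory
   cues presented back-to-back with no gap (A then B; C then D), six pair
   trials each, in blocks, with no reward.
2. **Conditioning** (6 sessions x 12 trials): B presented with reward
   deliveries 1, 4 and 7 s after cue onset; D presented unrewarded; trials
   in 3-trial blocks.
3. **Probe**: three rewarded-B and three D reminder trials interleaved,
   then six A and six C presentations, unrewarded.

Each trial is represented as a window starting 2 s before the first cue
onset (the pre-cue baseline used by the normalization) and ending 2 s after
the last cue offset. The 3-6 min inter-trial intervals carry no data and are
held only as metadata; a scale factor can compress them, which never touches
within-trial timing. The schedule builder enforces the structural guarantee
the design rests on: outside preconditioning, cue A never shares a trial
with (and is never contiguous to) a reward.

## The auROC normalization

For each neuron, each cue, and each 100-ms post-onset bin, the spike-count
distribution of that bin across trials (the *test* histogram) is compared
with the pooled distribution of all 100-ms bins in the 1-s pre-cue baseline
across all trials of that cue. Both histograms are jointly min-max
normalized to [0, 1]; a discrimination threshold is then swept from 0 to 1
in 0.01 steps, and at each threshold the fraction of test bins strictly
above it (hit rate) is plotted against the fraction of baseline bins
strictly above it (false-alarm rate). The area under this curve, with
endpoints (0,0) and (1,1) appended, is the normalized response: 0.5 means
no change from baseline, values above 0.5 excitation, below 0.5 inhibition.

Numerical choices worth stating explicitly:

* **Strict inequality at the threshold.** Counts exactly at a grid
  threshold are *not above* it. With counts min-max normalized onto the
  grid's own scale, ties at grid values occur; treating them as not-above
  makes identical test and baseline multisets trace the diagonal exactly.
* **Exact identity.** Identical multisets return exactly 0.5 (the
  implementation short-circuits this case rather than leaving the identity
  to floating-point summation).
* **Endpoints appended.** (0,0) and (1,1) close the curve so degenerate
  histograms integrate sensibly; the all-equal pooled case returns 0.5.
* **Baseline location.** The baseline is the 1 s immediately preceding cue
  onset, split into 100-ms bins and pooled across all trials of that cue
  (pooling per cue, not per neuron across cues).
* **Half-open bins.** A spike exactly on a bin boundary belongs to the
  later bin; a 1e-9-bin snap keeps this convention stable under
  floating-point alignment arithmetic.
* **Hit vs false-alarm.** The comparison distribution's exceedance fraction
  is used as the false-alarm (false-positive) rate; a ROC cannot be formed
  from a false-negative rate, so the normalization is defined this way
  deliberately.

The implementation is checked bin-by-bin against an independent brute-force
threshold-sweep oracle to 1e-12, and satisfies range, identity,
monotonicity and scale-invariance properties by construction.

## Classifying response types

Neurons are classified from the neuron-by-time matrix of auROC values over
the full 10-s cue-B window (which contains the three reward deliveries):

1. **PCA** (`response_pca()`): time bins are mean-centered but not
   variance-scaled — auROC values already share a common scale — and the
   first 3 components are kept. Component signs are fixed (largest-magnitude
   loading positive) so results do not depend on the underlying LAPACK
   routine.
2. **Complete-linkage clustering** (`cluster_neurons()`): agglomerative
   hierarchical clustering on Euclidean distances in component space, cut
   at exactly 3 clusters. The cut is defined by cluster count, not by a
   height criterion, since only the count is identifiable. Results are
   checked against a naive O(n^3) reference implementation.
3. **Archetype labels** (`label_archetypes()`): the cluster with the lowest
   mean auROC is `sustained_inhibited`; of the remaining two, the one with
   the larger transient index (onset-window mean minus late-window mean) is
   `phasic`, the other `sustained_excited`. Ties on a deciding statistic
   raise an error instead of being broken arbitrarily.

Independently, `classify_waveform()` applies the traditional criterion:
negative half-width above 450 microseconds and a positive-to-negative
deflection ratio above zero. Taken literally with magnitudes, that ratio is
always positive, so the implemented reading requires a genuinely positive
maximal deflection (deflections are stored signed); the threshold is
configurable for other conventions.

## Error-signal statistics

* `onset_reward_difference()`: mean auROC over the first 500 ms after cue-B
  onset minus the first 500 ms after the *first* reward delivery (the
  earliest unambiguous reward event, 1 s into B). `migration_correlation()`
  correlates this difference with the conditioning-session index across
  neuron-sessions; a positive correlation is the signature of the phasic
  peak migrating from reward to cue onset as learning proceeds.
  Neuron-sessions are treated as the observational unit.
* `phasic_contrast()` / `sustained_contrast()`: per-neuron baseline-
  subtracted mean firing rates (Hz) over the first 1 s, or the final 9 s,
  of a cue pair, with a paired two-sided t test. Rate units are the
  default; auROC units are available behind a flag. The baseline rate is
  pooled across all probe trials per neuron, so it cancels exactly in the
  paired contrast rather than adding estimation noise.
* `inferred_vs_cached_correlation()`: Pearson correlation across neurons
  between the B-D and A-C first-second contrasts (df = n-2).
* `behavior_stats()`: factorial ANOVAs on food-cup occupancy over
  rat x cue x session (conditioning) or rat x cue x trial (probe) cell
  means, and a one-way cue test for preconditioning. The behavior table
  carries a `rat_id` column because these designs need the rat factor.

No multiple-testing correction is applied: the analyses report unadjusted
tests at alpha = 0.05, and the reports say so.

## The synthetic-data generator

The generator exists so that every downstream stage has a ground truth.
Its defaults encode the study conditions; where magnitudes are simply not
reported anywhere (no firing rates, gains or variabilities are published
for any of the populations), values were chosen once to be physiologically
plausible and are stated here:

* **Baselines**: 6 Hz (phasic), 15 Hz (sustained-excited), 10 Hz
  (sustained-inhibited) — midbrain-typical rates giving workable spike
  counts at the task's trial counts.
* **Phasic transients**: 15 Hz peak gain, 50 ms latency, 200 ms exponential
  decay. The per-session learning trajectory is linear — the simplest shape
  consistent with a peak that is reward-dominated in session 1 and
  onset-dominated in the final session — interpolating transient weights
  between 0.25 and 1.
* **Probe coding strengths**: each phasic neuron draws a (B-D, A-C) pair
  from a bivariate normal with means (5, 4) Hz, SDs (6, 5) Hz and
  correlation `rho` (default 0.6; `rho = 0` is supported for null tests).
  The strengths act as rate increments over the first second of B and A
  respectively, so the measured first-second contrast estimates them
  directly. With the probe's 3 B/D and 6 A/C trials these settings imply a
  population effect size near d = 0.75 for the cached-value contrast at
  n = 52, comparable to the magnitude of reported probe-test effects.
* **Sustained inferred value**: cue A additionally carries 0.3 x its A-C
  coding strength as sustained rate over the final 9 s (set
  `sustained_transfer = 0` to ablate it).
* **Trial-to-trial variability**: a log-normal gain (sd 0.25, truncated to
  [0.25, 4]) multiplies all modulation components per trial.
* **Rectification**: rates are clipped at zero after summing components,
  since Poisson intensities must be non-negative.

Spike times are drawn by exact inhomogeneous-Poisson thinning (the proposal
bound is the baseline plus the summed positive component amplitudes at the
largest trial gain), vectorized across the trials of a trial type.
Identical specifications and seeds give byte-identical outputs.

Behaviour is simulated as Beta-distributed per-trial occupancy fractions
whose means encode the expected pattern: a common low rate (5%) for all
cues in preconditioning, B rising linearly to 70% across conditioning while
D stays at base, and at probe A at 40% against C at 8%.

What the generator deliberately does not emulate: spike-sorting noise and
unit drift, bursting and refractory structure, session-to-session unit
turnover, and correlated noise across neurons. Passing recovery tests on
generator output therefore demonstrates that the pipeline is a faithful
implementation of the analysis — not that the analysis is robust to every
idiosyncrasy of real recordings.

## Agent simulations

Both agents use a complete serial compound representation: 1-s time steps,
one state per cue per step, reward magnitude 1 per delivery (received on
entering the state whose step begins at the delivery time), and a
background inter-trial state whose value is pinned at zero — the long,
variable intervals carry no predictive structure, and pinning the
background state keeps the onset error interpretable as `gamma * V(first
cue state)`.

* `run_model_free()` is tabular TD(0). Its per-step trace records the
  pre-update values, so the reported deltas satisfy
  `delta = r + gamma * V(s') - V(s)` exactly, and the probe-onset error for
  cue A is *analytically* zero: no reward ever follows A in phase 1, so
  every value along its chain stays zero, and A is absent from phase 2.
* `run_model_based()` learns an incremental one-step transition model in
  all phases (structure learning in phase 1 proceeds without any reward)
  and reward-on-entry estimates where rewards occur, then evaluates
  `V = T (R + gamma V)` by fixed-point iteration on the model as learned at
  the end of phase 2. The mechanism choice — explicit transition model plus
  policy evaluation — is an illustrative member of the model-based class,
  not a mechanistic claim; the interface leaves room for variants such as
  successor representations.

`compare_agents()` runs both on the identical deterministic episode
sequence and tabulates probe-onset signals: the model-free agent shows
B-D > 0 and A-C = 0; the model-based agent shows both contrasts positive.
This dissociation holds across a grid of learning rates and discounts.

## Problem sizes and calibration checks

The test suite validates the pipeline at the scales the design calls for:
archetype recovery on 300 neurons (100 per archetype, one fixed seed,
accuracy at least 0.90); correlation recovery on 200 replicate populations
of 52 phasic neurons (the mean recovered r must fall inside the 95%
sampling interval of rho = 0.6 at n = 52 — measurement noise attenuates
the recovered value, and these conditions keep the attenuation within
sampling error); peak migration on 300 neuron-sessions (50 neurons x 6
sessions). Null calibrations (rho = 0; a flat learning trajectory) check
that the corresponding tests reject at about the nominal 5% level over 200
replicates; because the size of a test does not depend on the number of
neurons per replicate, the null replicates use smaller populations than
the positive checks. Monte-Carlo sampler calibrations compare empirical
trial counts against numerically integrated rate templates within three
standard errors.

## Known limitations

* The original recordings are not publicly deposited, so the package's
  correctness claims are property-based (oracle equivalence, analytic
  identities, parameter recovery on synthetic data); the printed
  inferential statistics of any particular dataset are not reproduction
  targets.
* The classifier assumes the three archetypes are present and separable;
  populations missing an archetype produce an ambiguity error rather than
  a forced labelling.
* The auROC statistic pools baseline bins per cue. Pooling per neuron
  across cues is a plausible alternative reading; it would change values
  only if pre-cue firing differed systematically between cues.
* Agents are deliberately minimal: no eligibility traces, no function
  approximation, no hybrid arbitration, and no fitting to neural data.
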