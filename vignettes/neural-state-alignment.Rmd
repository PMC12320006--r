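---
title: "Neural state segmentation and stimulus-change alignment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural state segmentation and stimulus-change alignment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During naturalistic stimulation (e.g. movie watching), multivoxel fMRI
activity in a brain region passes through a sequence of *neural states*:
temporally contiguous periods with a relatively stable activity pattern,
separated by rapid transitions.  This package asks whether the transitions
— neural state boundaries — align with identifiable changes in the
stimulus: cuts and low-level visual changes, changes of depicted location,
spectral changes in the soundtrack, speech onsets and offsets, or the
event boundaries that human observers report.  Because such stimulus
features are strongly intercorrelated in any real movie, the alignment
question is only meaningful after correcting each feature for the others,
and because both timelines are strongly autocorrelated, significance must
come from a null model that respects the temporal structure of the states.

The package provides the full chain: data-driven state segmentation,
construction of per-volume stimulus-change timelines, covariate-corrected
partial correlation, a duration-preserving permutation null, and a
searchlight variant with false-discovery-rate control — together with a
synthetic-data generator that plants a known ground truth so every stage
can be validated end to end.

## State segmentation

`greedySegment()` segments a voxels × time matrix (one run, typically a
group average) into temporally contiguous states.  The fit of a candidate
segmentation is the mean, over volumes, of the Pearson correlation between
each volume's voxel pattern and the mean pattern of the state containing
it (`fitScore()`).  Single-volume states contribute correlation 1;
zero-variance volumes contribute 0 with a warning.

Each greedy iteration considers every contiguous interval strictly inside
an existing state as a candidate new state.  An interval with both edges
interior contributes two new boundaries at once; an interval sharing an
edge with its host state contributes one.  The candidate maximizing the
fit is inserted, and — with `finetune = 1`, the default — every boundary
is then visited once, left to right, and shifted by one volume when that
strictly improves the fit.  The boundary set reached at each state count
is recorded as a snapshot, up to `kMax` (default: half the number of
volumes).  Because an iteration may add two boundaries, a particular state
count can be skipped; analyses that need a specific count (for instance a
planted ground truth) should cap `kMax` at that count, which restricts the
final iterations to single insertions.

Numerical choices worth stating:

* All candidate evaluations reduce to O(1) lookups in two-dimensional
  prefix sums of weighted Gram matrices.  Writing $c_t$ for the
  voxel-centred pattern of volume $t$, $u_t = c_t / \lVert c_t \rVert$ and
  $w_t = \lVert c_t \rVert$, the summed correlation of the volumes of a
  contiguous segment $I$ with the segment's mean pattern is
  $Q(I) / \sqrt{S(I)}$ with
  $Q(I) = \sum_{t,s \in I} w_s\, u_t^\top u_s$ and
  $S(I) = \sum_{t,s \in I} w_t w_s\, u_t^\top u_s$, because centring
  commutes with averaging.  This makes an iteration O(T²) regardless of
  the voxel count.
* Candidate gains within `1e-8` of the maximum are treated as exact ties,
  and the earliest interval (smallest start, then end) wins.  On noiseless
  data many candidates tie at machine precision; without the tolerance the
  winner would be decided by rounding dust, and a two-boundary insertion
  could spuriously beat the equivalent single insertion.
* A finetuning shift must likewise exceed the tolerance to be accepted.

`selectK()` chooses the number of states: for every snapshot it compares
volume-pair correlations within states against pairs in *temporally
adjacent* states with a pooled two-sample t statistic, and picks the
count maximizing the statistic.  The restriction to adjacent states is
deliberate — in long naturalistic runs, distant states may legitimately
revisit a pattern, and counting such pairs as "between" would penalize
correct segmentations.  One known failure mode: on exactly noiseless data
with few states, shattering a state into single-volume fragments can pull
the between-state mean toward the dominant pattern correlation and
inflate the statistic, so the selected count can exceed the truth.  With
realistic noise, more states, or longer runs (the regimes the tests
exercise: 8 states over 120 volumes) the statistic peaks at the planted
count.

`boundaryStrengths()` scores each boundary as 1 minus the Pearson
correlation between the mean patterns of the two flanking states, giving
values in [0, 2] (0 = identical flanking patterns, 2 = perfectly
anticorrelated).  `toTimeline()` expands a segmentation into a per-volume
vector holding 0 between boundaries and the strength at each boundary; a
boundary at position $b$ means a new state starts at volume $b + 1$.

## Annotation timelines

Raw annotation sources become per-volume change timelines:

* `hashChangeTimeline()` — Hamming distance between consecutive
  perceptual-hash bit-vectors, divided by the bit-vector length (the
  normalization maps to [0, 1]; the constant is a documented choice).
* `cosineChangeTimeline()` — cosine distance between consecutive feature
  vectors (e.g. spatially pooled network-layer activations), optionally
  scaled so the maximum is exactly 1.  The scaling scope is per category
  (per layer) over the whole concatenated movie: pass all frames at once,
  or scale after concatenation with `scaleToUnitMax()`.
* `mfccChangeTimeline()` — audio coefficients are first delayed, then
  averaged per volume, then converted to cosine distances between
  consecutive volumes and scaled to unit maximum per run.  The asymmetric
  scaling scopes (per run for audio, whole movie for visual layers) follow
  the conventions of the annotation sources they emulate; both are
  available.
* `speechChangeTimeline()` — words are merged into speech periods (a gap
  shorter than one TR keeps a period open); the start of each speech
  period and of each silence period is a change.  Silence is defined as at
  least one TR without words, and begins at the offset of the last word
  before the qualifying gap — the natural reading of "start of a silence
  period"; the alternative convention (offset + TR) was considered and
  rejected because it would date the change after the stimulus evidence.
  A change at time 0 is dropped.
* `eventBoundaries()` — button presses are shifted back by the response
  time (default 0.9 s) and clustered across observers by single linkage
  with a gap threshold (default 1 s — the sources only say "close in
  time", so the window is explicit and tunable); clusters with at least
  `minSubjects` (default 5) distinct observers yield one boundary at the
  cluster mean.

`shiftAndBin()` then adds the hemodynamic delay (default 4.5 s, a
parameter of the analysis, not re-estimated here) and bins changes from
seconds onto the volume grid: a volume is marked when a shifted change
falls inside its window `[v·TR, (v+1)·TR)`; continuous series take the
within-window mean (maximum available via a flag — the mean is the
rate-preserving choice for change magnitudes).  `concatenateRuns()` joins
runs and records their lengths so permutations stay within runs.

## Alignment testing

`partialCorrelation()` residualizes both timelines on an intercept plus
the covariate matrix by least squares and correlates the residuals.  The
covariates for each annotation of interest come from a
`CovariateLedger`: each category is corrected for every category outside
its own group and never for same-group categories (which carry the same
information — small- and large-scale locations are nested, a shot change
accompanies every visual change).  `defaultCovariateLedger()` encodes the
standard table; custom ledgers are validated against the self- and
same-group rules.

Parametric p-values are invalid for these autocorrelated series, so
`permutationTest()` builds the null by shuffling the *order* of states
within each run, keeping the state count and every state's duration
intact (`permuteStates()`), re-concatenating, and re-computing the
partial correlation.  Strength handling under the shuffle is a documented
choice: each strength travels with the state it opens; the first state
opens no boundary, and its empty slot is dropped from the permuted
sequence, so the remaining strengths are assigned in permuted order to
the rebuilt boundaries in temporal order.  This preserves the full
multiset of strengths and durations on every draw (asserted in the
tests).  The annotation is residualized once; each permuted timeline is
residualized against the same covariate matrix, which is algebraically
identical to re-running the full partial correlation and much cheaper.

The p-value is one-tailed ("greater") and equals the fraction of null
values greater than or equal to the observation — the literal counting
rule, which can return 0.  A `(count + 1) / (n + 1)` variant is available
behind a flag for users who want guaranteed-valid p-values; it is off by
default to match the counting convention.  `bonferroni()` multiplies by
the number of tests (e.g. ROIs) and caps at 1.

## Searchlight analysis

`buildSearchlights()` tiles a 3D mask with spheres: candidate centers on
a regular grid (spacing 2 voxels) anchored at the minimum corner of the
mask's bounding box (a deterministic, mask-relative origin), members are
in-mask voxels within Euclidean distance 3.5 voxels (boundary inclusive,
voxel units; isotropic grids make voxel and mm spheres equivalent up to
scale), and searchlights with fewer than 20 members are dropped.  An
unbounded interior sphere of radius 3.5 contains 179 lattice voxels.
`runSearchlightAnalysis()` repeats the ROI analysis per searchlight
(default 1000 permutations, per-searchlight seeds derived from the master
seed); `fdrCorrect()` applies Benjamini–Hochberg across searchlights
(implemented on `stats::p.adjust`, with the highest surviving raw p
reported); `voxelAggregate()` marks a voxel significant only when the
*mean* p of all searchlights covering it is strictly below the highest
surviving p.  Searchlights with missing p (degenerate data) are excluded
from both the FDR and the voxel means; uncovered voxels are never
significant.

## The synthetic-data generator

`simulateGroundTruth()` plants, per run, a set of boundaries with a
minimum state duration (default 3 volumes) and one i.i.d. standard-normal
voxel pattern per state, so the expected correlation between state means
is near zero and detectability is governed by `snr` alone — the ratio of
pattern SD to noise SD.  `simulateRun()` emits one z-scored voxels × time
matrix per subject (block-structured signal plus white Gaussian noise;
temporal AR(1) correlation is available behind a knob, default off,
because the generator should not assert an autocorrelation the data may
not have).  Defaults follow the emulated acquisition: TR 2 s, 15
subjects, hemodynamic delay 4.5 s.  `groupAverage()` averages subjects.

`simulateAnnotationSources()` plants stimulus changes: a category with
coupling $c$ places changes at a fraction $c$ of the boundaries
(selected by count), at the boundary's volume onset minus the delay,
plus uniformly placed distractor changes.  For partially coupled
categories the distractors keep a one-volume gap from true boundaries so
the coupled fraction is unambiguous; for a fully uncoupled category
(coupling 0) the gap is dropped, because the null-calibration tests
require genuine independence between changes and boundaries, and the gap
would induce a negative dependence.  Covariate categories can co-occur
with a target category at a configurable rate, emulating the high
inter-annotation correlations of real movie annotations.  Sources are
delivered in the shapes the annotation builders consume — change times,
word tables, press tables, or per-frame magnitude series — so the whole
annotation pathway is exercised, not just its output format.

What the generator does *not* emulate: hemodynamic convolution of the
neural signal itself (states are modeled directly in volume space; the
delay applies to annotations only), head motion, physiological noise, and
spatial noise correlations.  Passing tests therefore show that the
algorithms are correct under the stated model, not that real fMRI data
satisfy that model.

## Pipeline, reproducibility and problem sizes

`runConfig()` collects all parameters (YAML round-trip via
`writeRunConfigYaml()` / `readRunConfigYaml()`); a bare configuration
reproduces the standard settings: delay 4.5 s, `kMax` = half the run
length, finetuning on, 10000 permutations per test.  `runPipeline()`
chains simulation → z-scoring (population-SD convention, recorded in the
manifest) → group averaging → per-run segmentation → annotation building
→ alignment tests with ledger covariates → Bonferroni, and writes JSON/
TSV outputs plus a manifest with the config hash and per-file checksums.
All randomness derives from the config seed; reruns are byte-identical.

The validation suite runs at desk scale: segmentation recovery uses 120
volumes, 50 voxels and 8 states (10 noiseless and 20 noisy replicates);
null calibration uses 200 synthetic datasets at 1000 permutations;
sensitivity uses 50 datasets per coupling level; searchlight geometry is
checked against brute-force enumeration on a 12³ grid.  These sizes were
chosen as the smallest at which the statistical claims are sharp (e.g.
the binomial 95% band around a 5% type-I rate at 200 datasets is
2–8%).

## Known limitations

* The state-count statistic can over-segment exactly noiseless data with
  few states (see above); it is intended for data with noise.
* The greedy search is not globally optimal; a boundary spent on a
  spurious split of a long state cannot be reclaimed for a short true
  state at the same count.  With 3–4-volume states at snr 2 this causes
  occasional misses (the recovery tests bound the rate).
* The permutation null conditions on the observed segmentation; it tests
  the alignment of *these* boundaries, not segmentation uncertainty.
* Because the generator maps boundaries back to stimulus time, the first
  `ceil(delay / TR)` volumes of a run cannot carry planted changes; with
  the counting p-value this makes null p-values slightly conservative at
  sparse annotations.
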