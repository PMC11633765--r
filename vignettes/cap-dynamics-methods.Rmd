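---
title: "Methods: seed-gated co-activation pattern dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-gated co-activation pattern dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`capdyn` treats a resting-state scan as a sequence of transient brain
states gated by a seed region. The underlying assumptions are:

* at moments when the seed is strongly active, the whole-brain frame is an
  instance of one of a small number of spatial co-activation patterns (CAPs);
* those patterns are shared across the reference population (healthy
  controls), so patient frames can be matched against reference maps;
* group differences, if any, live in the *temporal organization* of the
  states — how often they are entered, how long they last, and how likely
  the brain is to stay in or switch between them — rather than necessarily in
  the maps themselves.

The analysis pipeline is: preprocess each subject's masked frames-by-voxels
matrix; standardize the seed time course and keep high-activation frames;
pool the control frames and cluster them; derive each subject's per-timepoint
state label; compute temporal metrics; compare groups with covariate
adjustment and FDR control.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `fd_threshold_mm` | 0.5 | mm | Power's scrubbing criterion; frames above it are censored (flagged, never deleted). |
| `head_radius_mm` | 50 | mm | converts rotations to arc length in the FD sum; the standard convention. |
| `highpass_hz` | 0.01 | Hz | drift cutoff; implemented as discrete-cosine basis regression. |
| `select_value` | 0.84 | z (SD) | the 80th standard-normal percentile; "high-amplitude" seed events. |
| `k_range` | 2..8 (pipeline), 2..15 supported | — | candidate cluster counts scanned by consensus clustering. |
| `n_subsamples`, `subsample_frac` | 100, 0.8 | — | consensus resampling depth; 100 × 80% is the common setting. |
| `pac_bounds` | (0.1, 0.9) | — | consensus values strictly inside count as ambiguous. |
| `assign_percentile` | 0.05 | — | a frame must reach its best CAP's 5th-percentile member correlation to be assigned. |
| `gap_mode` | `"strict"` | — | transition pairing across unselected/censored frames (see below). |
| `tr` | 1.3 | s | repetition time; durations are run lengths × TR. |

## The synthetic cohort generator

`sim_config()` defaults define the study conditions the package validates
itself against: two groups (control, patient) of 14 subjects, 300 frames at
TR = 1.3 s on a 12×12×8 voxel grid, three planted spatial patterns, and a
latent first-order Markov chain per subject over {baseline, state 1..3}.
The baseline state is explicit and seed-quiescent so that frame selection has
a real signal to find; each pattern carries a positive loading on a small
2×2×2 seed nucleus. From baseline the chain enters each state with
probability 0.06 per frame; states persist with probability 0.50 (controls)
and return mostly to baseline, giving state occupancies near 10% each and
run lengths of ~2 frames — dynamics on the time scale the frame-selection
design assumes. The patient group's state self-transition probabilities are
boosted by +0.10 (taken from the return-to-baseline mass), a pure
"state persistence" effect whose through-pipeline effect size (Cohen's d
roughly 0.5–0.8 on the pooled self-transition fraction) is in the range such
clinical resting-state studies report. Covariates (age 20–58, sex,
medication flag, depression and state-anxiety scores, an overdispersed
seizure count in patients) are drawn independently of group unless an
explicit confound effect is requested, so the adjustment stage can be tested
under both null and confounded scenarios.

Two generator details matter and are deliberate:

* **Patterns are spatially zero-mean.** Real z-scored CAP maps have balanced
  positive and negative deflections, so the global signal carries almost no
  state information. All-positive blobs would make global-signal regression
  (on by default) subtract the state time course itself.
* **Motion spikes are step jumps** of 0.6 mm on one translation axis, so each
  spike deterministically produces exactly one frame above the 0.5 mm FD
  threshold (expected excluded count = spike rate × frames).

What the generator does **not** emulate: hemodynamic convolution and
autocorrelated physiological noise, spatial noise correlations, subject-level
map variability, and registration error. Passing tests therefore demonstrate
the correctness and calibration of the *procedure* under its own assumptions,
not performance on real BOLD data.

A single integer seed fans out to fixed per-subject substreams
(`rng_seed + 7919·i`), so cohorts regenerate bit-identically and subjects are
independent streams.

## Numerical choices

* **High-pass filtering** regresses out the orthonormalized discrete-cosine
  basis functions with frequency below the cutoff (plus the constant), the
  drift model used by GLM-based fMRI software. It is exactly linear and
  idempotent. Attenuation is measured in RMS amplitude: a 0.002 Hz tone is
  reduced below 3% while a 0.1 Hz tone keeps >99%; residual edge ripple is
  inherent to cosine drift models.
* **z-scoring** uses valid frames only, sample SD (n−1); zero-variance voxels
  become all-zero columns and are flagged rather than erroring.
* **Seed course**: probabilistic seed weights are used as-is in a normalized
  weighted mean (binarizing would discard atlas information for small
  nuclei); the course is re-standardized over valid frames before
  thresholding, so the 0.84 SD cut refers to the seed course's own scale.
  Selecting on the raw weighted mean instead is available via
  `mode = "top_fraction"`, which fixes the selected count rather than the
  threshold; the two coincide only under normality, and the realized count is
  always recorded.
* **Consensus clustering** uses single-start k-means per subsample (the usual
  convention — local-optimum scatter is part of the instability PAC
  measures), with all candidate K values scored on the *same* subsample
  draws. Pairs never co-sampled are excluded from PAC rather than counted as
  zero. K selection automates the visual-inspection step by maximizing
  1 − PAC, ties toward the smaller K with a warning; the full PAC table and
  (optionally) consensus matrices are kept for inspection.
* **Reference thresholds are leave-one-out.** Each CAP's member-correlation
  distribution is computed against the CAP map rebuilt without the member
  frame. Plain in-sample correlations are optimistically biased (each frame
  contributes 1/n of its own map), which inflates the 5th-percentile
  threshold and silently over-rejects out-of-sample frames — in simulation,
  patient unassignment fell from ~15% to near the nominal 5–10% once the
  bias was removed.
* **Assignment ties** (a frame equally correlated with two maps) break toward
  the lower CAP index, deterministically. Zero-variance frames are
  unassignable and flagged.
* **Controls pass through the same assignment threshold as patients** by
  default (`reassign_controls = TRUE`). The asymmetric variant — controls
  keep their k-means labels — is available, but the symmetric procedure is
  the one whose reported group contrasts are unbiased: with asymmetric
  assignment only patients lose frames to the threshold, which systematically
  dilutes their observed dynamics.
* **Degenerate inputs** degrade rather than fail: empty frame selections warn
  and return empty sets; metrics for a CAP never visited are `NA`, not zero
  (a zero would fabricate certainty about an unobserved row); groups with
  fewer than 3 complete cases yield `NA` comparison rows with a warning;
  covariate columns that are collinear or exhaust the degrees of freedom are
  dropped with a warning, never silently.

## Transition estimation and gap handling

The state sequence contains gaps — censored frames, frames below the seed
threshold, unassigned frames — and the central under-determined choice is
what counts as a transition.

* `gap_mode = "strict"` (default): only originally adjacent CAP–CAP pairs
  count. This is the literal reading of "state at t to state at t+1", but it
  conditions on the *next frame also being selected*: runs that end by the
  seed going quiet contribute no pair, so most of a persistence difference is
  conditioned away. In simulation a planted +0.10 self-transition boost
  survives as only ~0.015 in the strict estimate.
* `gap_mode = "collapse"`: gap labels are dropped and successive CAP frames
  are paired across gaps. This is coarser (a pair may span seconds of
  unselected time) but far more sensitive to persistence, because longer runs
  now yield proportionally more self-pairs per run ending. The planted boost
  survives as ~0.03–0.04, and its sign is recovered in ≈19/20 replicate
  cohorts at the default study size — which is also roughly the ceiling: a
  d ≈ 0.6 effect at n = 14 per group cannot be sign-recovered much more
  reliably by any estimator.

Both modes share the same counting rules otherwise: rows with zero observed
pairs propagate as missing into group statistics, and entries/durations are
always computed on the original timeline (gaps break runs).

## Statistics

Group comparisons fit `metric ~ group + covariates` on complete cases
(`lm`-equivalent via QR), report the group coefficient with its t and
two-sided p, and compute Cohen's d on covariate-residualized values with
pooled-SD standardization — so d matches the adjusted contrast, with the
patient-minus-control sign convention stated in the output. FDR correction
is Benjamini–Hochberg within metric families (the K² transition cells form
one family; entries, durations and occupancies each their own), mirroring how
these metrics are reported separately. The Welch-from-summary helper exists
because descriptive tables print (mean, SD, n) triplets; the Mann–Whitney
helper reports the continuity-corrected, tie-adjusted normal Z (the printed
statistic) with an exact-distribution p for small tie-free samples — the
normal approximation's worst-case two-sided-p error on the n = 8/8 lattice
is 0.011, so exactness is the better default where it is free. Seizure-count
correlations use Spearman rank correlation, as the counts are heavily
overdispersed.

## Problem sizes

The package's own validation runs at sizes chosen to make the statistical
claims meaningful while staying desk-scale: full synthetic cohorts
(28 subjects × 300 frames × 1152 voxels) for end-to-end checks; 10,000-frame
chains for estimator-consistency bounds (max absolute error < 0.02); 20
replicate cohorts for sign-recovery rates; 1,000-replicate nulls for type-I
calibration (0.05 ± 0.02); and 20 replicates of 200 frames × 500 voxels for
PAC-based model selection, where K = 3 is recovered unanimously.

## Known limitations

* The pipeline consumes already-aligned, already-registered series; spatial
  normalization and atlas-space resampling are out of scope.
* Consensus clustering at full scan ranges (K up to 15) on thousands of
  pooled frames is memory- and CPU-heavy (the consensus matrices are
  n × n); `keep_consensus = FALSE` keeps only the PAC curve.
* Entries are raw counts, not rates: session-length differences are handled
  through the excluded-frame covariate in the group model, not by
  normalization.
* With 14 subjects per group, single-cohort inference on transition cells is
  underpowered for realistic effects; the package's replicate-level checks
  quantify exactly how much signal survives each estimator, and users should
  expect sign-level, not cell-level, conclusions at this scale.
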