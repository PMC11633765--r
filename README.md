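# capdyn

Seed-based co-activation pattern (CAP) dynamics for resting-state fMRI.

## What this package does

Resting-state BOLD activity is not a single static network but a sequence of
transient whole-brain configurations. Seed-based CAP analysis characterizes
those configurations relative to a small region of interest (here typically a
brainstem nucleus such as the locus coeruleus): the moments when the seed is
highly active are collected, the corresponding whole-brain frames are
clustered into a few spatial co-activation patterns, and each subject's scan
becomes a labeled state sequence whose temporal statistics — entries,
durations, occupancies, and the transition probability matrix — can be
compared between groups.

`capdyn` implements that workflow end to end for researchers analyzing
already-aligned 4D volume series:

1. **Preprocessing** — nuisance regression (constant/linear/quadratic trends,
   WM/CSF means, 6 motion parameters, optional global signal), discrete-cosine
   high-pass filtering at 0.01 Hz, optional Gaussian smoothing, motion
   scrubbing by Power's framewise displacement (FD > 0.5 mm), per-voxel
   z-scoring over valid frames.
2. **Frame selection** — the seed's weighted-mean time course is standardized
   and frames above 0.84 SD (the 80th standard-normal percentile) are kept.
3. **Model selection and fitting** — consensus clustering over a range of K
   scores each candidate by the proportion of ambiguously clustered pairs
   (PAC); `cap_fit()` then runs k-means at the chosen K and returns a classed
   model object with `print`/`summary`/`coef`/`predict`/`plot` methods.
4. **Assignment** — held-out frames are matched to their best-correlated
   reference CAP, and dropped as unassigned when the correlation falls below
   that CAP's 5th-percentile member-correlation threshold.
5. **Dynamics** — per subject: entries (run counts), mean durations
   (mean run length × TR, in seconds), occupancy, and the row-stochastic
   transition matrix `T`, with `T[m, n] = P(state n at t+1 | state m at t)`.
6. **Inference** — covariate-adjusted linear-model group comparisons
   (age, sex, medication, depression and anxiety scores, excluded- and
   selected-frame counts) with Benjamini–Hochberg FDR per metric family,
   Cohen's d on covariate-residualized values, plus Welch-from-summary and
   Mann–Whitney helpers, Spearman correlation with seizure counts, and
   atlas-overlap summaries of thresholded CAP maps.

A synthetic cohort generator (`sim_config()`, `generate_cohort()`) plants a
known latent Markov state structure — two groups of 14 subjects, 300 frames
at TR = 1.3 s, three spatial patterns gated by a small seed nucleus, motion
spikes, and clinical-scale covariates — so every stage of the pipeline is
testable without access to patient data.

## Worked example

```r
library(capdyn)

set.seed(1)
cfg <- sim_config(rng_seed = 11)        # 2 x 14 subjects, 300 frames, K_true = 3
coh <- generate_cohort(cfg)
pl  <- run_cap_pipeline(coh, k = 3, rng_seed = 5)
print(pl$caps)
#> <cap_set> 3 co-activation patterns over 1152 voxels (1057 reference frames)
#>   CAP1: 359 frames (34.0%), assignment r >= 0.148
#>   CAP2: 354 frames (33.5%), assignment r >= 0.156
#>   CAP3: 344 frames (32.5%), assignment r >= 0.155
```

The fitted `cap_set` shows the three recovered patterns, how many pooled
control frames belong to each (CAP1 is always the most occupied), and the
per-CAP correlation threshold below which a held-out frame is left
unassigned. The group comparison table reports, per metric, the
covariate-adjusted patient-minus-control difference, t, raw and FDR-adjusted
p, and Cohen's d:

```r
gr <- pl$group_result
gr[gr$metric %in% c("T_1_1", "T_2_2", "T_3_3"), ]
#>  metric     family   diff      t df     p      d n_control n_patient p_fdr
#>   T_1_1 transition  0.056  1.613 19 0.123  0.685        14        14 0.370
#>   T_2_2 transition -0.036 -0.518 18 0.611 -0.218        14        13 0.786
#>   T_3_3 transition  0.065  1.905 19 0.072  0.807        14        14 0.324
```

Here the generator planted a +0.10 self-transition (state persistence) boost
in the patient group; the diagonal cells trend positive at this single-seed
cohort size, and the sign is recovered reliably across replicate cohorts
(see the methods vignette for what single-cohort power one should expect).

To leave K to the data instead of fixing it, omit `k`: the pipeline runs
consensus clustering over `k_range` and picks the K maximizing 1 − PAC
(`pl$consensus` keeps the full stability table).

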