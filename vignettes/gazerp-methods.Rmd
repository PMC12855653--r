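---
title: "Models and methods behind gazerp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gazerp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gazerp)
```

`gazerp` analyzes simultaneous eye-tracking and EEG recordings from a
2 × 2 within-subject design — face race (Asian, White) × mask condition
(masked, unmasked) — in which participants freely view faces while their
fixations and event-related potentials are recorded, plus a separate
speeded social-categorization task. This vignette explains the models,
the choices we made where the methodology was genuinely open, and what
the synthetic-data generator does and does not emulate.

## Scanpath hidden Markov models

A participant's fixation sequences in one condition are modeled by a
hidden Markov model whose hidden states are regions of interest (ROIs):
2-D Gaussian densities over screen-pixel positions (origin top-left, y
increasing downward, 1920 × 1080 frame — the eye-tracker convention,
recorded in every cohort manifest). The chain has a start-probability
vector and a row-stochastic transition matrix; fixation durations are
not part of the emission model, following the EMHMM convention of
modeling spatial pattern only.

### Variational-Bayes fitting and model selection

`fit_vbhmm()` uses the conjugate variational scheme: symmetric Dirichlet
priors (α = 1) on the start vector and each transition row, and
Normal-Wishart priors on each ROI. The prior hyperparameters
(`vb_hyper()`) are weakly informative: the ROI mean prior sits at the
frame center with a β of 0.01 (essentially flat over the screen), and
the Wishart scale corresponds to a prior ROI standard deviation of
200 px with ν = 3, the smallest integer degrees of freedom that keep the
prior proper in 2-D without dominating small samples.

The E step runs a scaled forward-backward pass with the
expected-log-parameter weights; the evidence lower bound (ELBO) is the
accumulated forward log-normalizer minus the Dirichlet and
Normal-Wishart KL terms, evaluated after every E step. The ELBO is
non-decreasing across iterations (a property the test suite asserts on
every fit) and iteration stops at a relative ELBO change below 1e-5 or
200 iterations. Five k-means-seeded restarts are the default; the best
ELBO wins. All randomness flows through an explicit seed, so fits are
reproducible.

`select_hmm()` fits each K in 1..5 and returns the model with the
highest ELBO, breaking exact ties toward the smaller K (the simpler
model). Degenerate input — all fixations identical — produces a
prior-regularized fit with a warning rather than a failure.

### Clustering into representative patterns

`cluster_hmms()` groups the individual models into two representative
patterns. We implement hierarchical EM on *virtual samples*: each input
model emits `n_virtual` sequences of length `tau` from its own
generative process, cluster responsibilities follow the total
log-likelihood of those sequences under the current group models, and
each group model is re-estimated by weighted Baum-Welch (with a small
covariance ridge) on the pooled virtual sequences. This Monte-Carlo
flavor of hierarchical EM uses the same interface (virtual sample count
and length) as the closed-form variational variant and recovers planted
partitions exactly in our tests; we chose it because its E step is a
plain likelihood evaluation, which keeps the whole procedure auditable
against the forward-algorithm oracle. Hard assignments break exact ties
toward the lowest cluster index, and clusters are relabeled so cluster 1
is the vertically highest (eyes-focused) pattern — making downstream
"pattern A minus pattern B" contrasts an eyes-nose scale by
construction.

By default all four race × mask conditions are pooled for clustering
(4 models × N participants enter one clustering run); fitting only the
unmasked conditions and clustering those reproduces the "typical
pattern" grouping used for the between-participant factor — the same
functions, applied to a filtered fixation table.

### Eyes-nose scale and entropy

`ab_scale(ll_a, ll_b)` is the exact normalized contrast
`(ll_a − ll_b) / (|ll_a| + |ll_b|)`; it is antisymmetric and lies in
(−1, 1) whenever both log-likelihoods are negative. The inputs are
*total* log-likelihoods over the participant's trials by default; a
per-sequence-mean option exists for unequal trial counts. The source
literature does not state which normalization was used — with both
log-likelihoods entering symmetrically the scale is insensitive to the
choice as long as it is applied consistently, and we default to the
total because the defining formula takes single whole-data numbers.

`hmm_entropy()` reports scanpath predictability. The cited information
theory gives no single formula for "the entropy of an HMM", so we
expose a decomposition and its parts: the transition term is the
entropy rate of the ROI chain (stationary-distribution-weighted row
entropies) and the emission term is the stationary-weighted Gaussian
differential entropy of the ROIs; the overall value is their sum, in
nats. Both terms respond in the intended direction: sharpening the
transition rows (elementwise power > 1, renormalized) never increases
the transition term — verified numerically over random matrices — and
tighter ROIs lower the emission term. For a chain without a unique
stationary distribution the prior weights are substituted with a
warning.

## ERP processing

Epochs span −200 to 1000 ms at 250 Hz. `baseline_correct()` removes the
per-channel, per-trial mean of the −200–0 ms span exactly.
`reject_artifacts()` drops any trial whose absolute voltage reaches
100 µV on any channel (strictly-below-threshold trials are kept) and
logs the offending channel; `exclude_low_retention()` applies the
inclusive ≥ 50 % epoch-retention rule per participant. Component
amplitudes are plain means over the component's channels, its window
with inclusive bounds (windows are specified in ms; at 250 Hz samples
fall every 4 ms), and the cell's trials. Upstream preprocessing —
filtering, line-noise removal, re-referencing, ICA — is deliberately
out of scope: those are standard third-party procedures, and both the
epochs reader and the synthetic generator deal in already-clean epochs.
Incorrect-response exclusion is a label filter (`filter_epochs()`)
applied before rejection. N170 left and right sites are analyzed
separately by default (a hemisphere-factor ANOVA can be run on the same
table). The default montage is a 61-channel extended 10-20 set; the
left N170 site is T7/TP7/P7/PO7, the standard left-hemisphere mirror of
the right site.

## Sliding-window decoding

Decoding uses surrogate ERPs to raise signal-to-noise: each class's
trials are randomly partitioned into near-equal groups (18 per race
class, 6 per identity) and each group is averaged into one surrogate.
Surrogates go into three class-balanced folds; features are per-channel
window means after downsampling to 125 Hz. A window is the half-open
100 ms span starting at its reported time, so every window holds 13
samples at 8 ms spacing and the start-time grid 0, 8, …, 896 ms covers
the 0–996 ms analysis range; start-time labeling is a convention we
document rather than a claim about the source analyses, and both the
window length and step are arguments.

The classifier is a linear SVM with C = 1 (the convention of the
decoding framework this follows; the sources do not state kernel or
regularization). Race uses the standard one-versus-one binary SVM;
identity uses one-versus-all with four binary machines and max-margin
prediction. z-normalization statistics come from the training folds
only and are applied unchanged to the test fold — the no-leakage
property is asserted by a label-shuffling test that must sit at chance.
Surrogate assignment *and* fold assignment are both re-drawn on each of
the 10 iterations; the iteration mean is the reported time course.

### Cluster-based permutation inference

`cluster_permutation_test()` forms pointwise t statistics across
participants (df = n − 1, two-tailed at α = 0.05 for cluster formation;
one-tailed available), collects maximal runs of consecutive
supra-threshold windows with a common sign, and sums their t values
into cluster masses. The null distribution of the maximal |mass| comes
from seeded participant-level sign flips of the deviation-from-chance
(for paired contrasts this is exactly within-participant condition
exchange); a cluster is significant when its observed |mass| exceeds
the null's 95th percentile, and the reported permutation p is
`(1 + #{null ≥ observed}) / (n_perm + 1)`, which is bounded below by
1/(n_perm + 1). The interaction test applies the same machinery to the
per-participant double difference
`(AsianUnmasked − AsianMasked) − (WhiteUnmasked − WhiteMasked)`.
Family-wise error calibration is checked by simulation in the test
suite (200 null datasets × 500 permutations).

## Group statistics

For 2 × 2 within designs every effect has one numerator degree of
freedom, so `rm_anova_2x2()` computes each F as the squared paired t of
the corresponding within-participant contrast — exact, with no
sphericity correction needed — and reports partial η². The mixed
2 × 2 × 2 ANOVA (`mixed_anova_2x2x2()`) uses the same contrast
decomposition with the typical-pattern group as the between factor
(unweighted group means; verified against the general linear model
implementation in `car` in the tests). `fisher_z_compare()` follows the
independent-samples r-to-z comparison with a one-tailed default, which
is how the comparison is conventionally reported in this literature
even when the two correlations share participants; treat its p as
approximate in that dependent case. RT summaries use correct,
within-deadline trials only — the sources are silent and this is the
common convention; timeouts are excluded rather than coded as errors.

## The synthetic cohort

`cohort_config()` defaults describe the study design the generator
emulates: ~55 participants, 2 × 2 within-subject conditions, 61-channel
epochs of −200–1000 ms at 250 Hz, two scanpath archetypes (eyes- vs
nose-focused, mixed 50/50), and a categorization task with 8 monoracial
trials per cell and 8 morphed trials per mask condition under a 1500 ms
deadline. The mask manipulation is modeled as (a) an upward ROI-mean
shift of 60 px in masked conditions and (b) exponentiation of the
transition rows by a sharpening factor of 2 followed by renormalization
— producing the two qualitative mask effects of interest, more
eyes-focused gaze and more consistent (lower-entropy) scanpaths, with
tunable magnitude. Behavioral defaults plant a small
masked-only own-race accuracy advantage, slower RTs for own-race faces
(lognormal, medians ~700 vs ~640 ms), and a morph own-race bias of
0.62; fixation durations are lognormal with a 250 ms median. EEG noise
is pink (1/f) noise mixed across channels through a random spatial
matrix — realistic spatial correlation without modeling a head — and
condition effects are smooth amplitude bumps on specified channels and
windows, with the ground truth recorded alongside.

What the generator does *not* emulate: ocular and muscle artifacts
(epochs are clean apart from the planted ±100 µV test cases),
volume-conducted component topographies, inter-trial dependence,
fixation-duration effects, or calibration drift. Passing tests
therefore demonstrate that the *algorithms* are correct and calibrated
on data with known structure — not that real recordings meet the
generator's assumptions.

## Problem sizes and numerical choices

The test suite runs everything at reduced-but-faithful sizes chosen so
the full suite completes in minutes on one CPU: decoding tests use 16
channels except the chance-level checks (61 channels, 20 iterations);
the family-wise-error simulation uses 200 null datasets × 500
permutations; the model-count check fits all 220 models of a
55-participant cohort with 10 trials per condition and K ∈ {1, 2}; the
end-to-end mask-effect check uses 12 participants. Covariance updates
carry a small ridge (25 px²) in the weighted Baum-Welch M step;
forward passes are scaled per step so sequences of 10⁴ fixations
evaluate without underflow; exact assignment ties in clustering go to
the lowest cluster index, and exact ELBO ties in model selection to the
smaller K.

## Known limitations

- The variational bound is a lower bound: K selection can be
  conservative when ROIs overlap heavily (adjacent eye ROIs may merge
  at small sample sizes).
- The virtual-sample clustering E step is stochastic given its seed;
  representatives vary slightly with `n_virtual` and `tau`, though hard
  assignments are stable in all tested regimes.
- The mixed ANOVA assumes two groups and complete within-cells;
  unbalanced designs use unweighted group means.
- The identity scheme assumes exactly four identities per decoded cell,
  mirroring the counterbalanced design it models.
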