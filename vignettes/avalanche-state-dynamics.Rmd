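---
title: "Avalanche brain-state dynamics: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Avalanche brain-state dynamics: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Resting-state neural recordings, source-reconstructed to a region-level
parcellation (typically the 90-region AAL atlas), spend most of their time in
low-amplitude fluctuations punctuated by brief, large, spatially coordinated
excursions — *neuronal avalanches*. `avstates` treats those excursions as the
informative events: it discards everything below a fixed amplitude threshold,
reduces each avalanche to the *set* of regions it recruited, and asks whether
those binary spatial patterns organise into a small number of recurrent brain
states with structured temporal transitions.

The pipeline is:

1. **Avalanche extraction.** Each region's time series is z-scored over the
   full recording (population SD) and binarised at a strict threshold,
   `|z| > 3` by default. An avalanche starts when at least one region is
   above threshold and ends when none is; each avalanche becomes a length-N
   binary pattern by OR-ing region activity over its interval.
2. **Diffusion embedding.** The unique patterns are reduced to 5 principal
   components, pairwise cosine distances are turned into an adaptive
   alpha-decay kernel (bandwidth at the 5th nearest neighbour, decay
   exponent 1), row-normalised into a diffusion operator, powered to a
   diffusion time chosen at the knee of the von Neumann entropy curve, and
   the potential distances (Euclidean distances between log-rows of the
   powered operator) are embedded in 3-D by metric MDS.
3. **State identification.** k-means (k = 7 by default) on the embedding;
   the number of states is diagnosed with elbow, silhouette and gap
   statistic.
4. **Dynamics.** Per-subject and pooled transition matrices over the
   chronological avalanche-label sequences, plus inter-subject variability.
5. **Validation.** Three permutation null models with a Shannon-entropy
   statistic over the state topographies.

## What the synthetic generator emulates

Real resting-state MEG cannot be redistributed, so every empirical result in
this package is computed on a synthetic cohort with planted ground truth.
`sim_params()` defaults define the study conditions:

| parameter | default | rationale |
|---|---|---|
| regions x rate x duration | 90 x 256 Hz x 360 s | the standard source-space resting-state setup |
| subjects | 18 | typical cohort size for this design |
| states / regions per state | 7 / 12 | seven distinguishable topographies over 90 regions |
| topography overlap | Jaccard <= 0.2 | states share some regions but stay identifiable |
| event rate x mean duration | 0.55 /s x 20 samples | ~200 avalanches per subject occupying ~4% of time points, matching the sparse-avalanche regime (a few seconds of avalanche activity per minute) |
| burst amplitude | 6 SD | events unambiguously cross the 3-SD threshold |
| recruitment probability | 0.8 | members participate stochastically, so patterns within a state vary |
| self-transition bias | 0.1 | self-transitions are the most probable transition (diagonal ~0.23) without making the chain degenerate |

**Fixture mode is the default.** The background is i.i.d. standard Gaussian
noise truncated at |z| = 2.9. This is a deliberate design choice: with 90
regions of *untruncated* Gaussian noise, some region exceeds 3 SD in about
22% of samples purely by chance, which floods the recording with thousands
of single-sample noise avalanches and contradicts the sparse regime the
pipeline targets (real region-level signals owe their supra-threshold
crossings almost entirely to the coordinated events themselves). Truncation
makes the planted events the only threshold crossings, so detection is
*exact* against ground truth and every downstream stage can be scored
against a known answer. Untruncated noise (`fixture_mode = FALSE`) and an
AR(1) background remain available for stress tests. During recruited event
samples in fixture mode the burst *replaces* the background at exactly
`burst_amplitude`; an additive burst on truncated noise could dip to
`amplitude - 2.9` and, after z-scoring inflates the SD, fall below
threshold, breaking exactness for no modelling benefit.

What the generator does **not** emulate: 1/f spectra and oscillations,
spatial noise correlations, graded (non-binary) recruitment within events,
heavy-tailed avalanche-size distributions, or volume-conduction leakage.
Passing tests therefore demonstrate that the *pipeline machinery* recovers
planted structure under realistic dimensions and sparsity — not that real
MEG contains seven states.

## Numerical choices

- **z-scoring** divides by the population SD (divisor T); at T ~ 9 x 10^4
  the difference from the sample SD is ~10^-5, but the convention must be
  fixed for exact tests. Ties at exactly the threshold are inactive
  (strictly-greater comparison).
- **Binarization mode**: `absolute` (|z|) by default — large deviations of
  either sign mark dynamical events; positive-only is a flag.
- **Kernel symmetrisation** averages the two directed kernels; the
  bandwidth neighbour excludes self, with ties broken by index order.
  Duplicate points would give a zero bandwidth, so the embedding always
  operates on *unique* patterns (and guards with an explicit error).
- **Diffusion time** defaults to the knee (maximum distance to chord) of
  the von Neumann entropy of the symmetrised operator's spectrum over
  t = 1..100, computed from one eigendecomposition rather than per-power
  SVDs. A flat curve falls back to t = 1 with a warning. An integer `t`
  can be forced.
- **Potential distances** floor probabilities at `1e-12 * max(P^t)` before
  the logarithm. A `potential = "diffused"` flag instead embeds
  `P^t D_cos (P^t)'`, covering the alternative reading of "using the
  diffusion probabilities directly to embed the cosine distances".
- **MDS** is SMACOF stress majorization initialised from classical MDS, so
  it is deterministic; the seed only matters for the degenerate fallback.
  Default cap 200 iterations, relative stress tolerance 1e-6 (a
  convergence warning is emitted otherwise — harmless for visualisation,
  and tightened by raising `mds_max_iter`).
- **k-means** uses `stats::kmeans` (Hartigan-Wong) under k-means++-style
  seeded initial centers, best of `n_init = 50` restarts by WCSS.
  Plain random restarts demonstrably strand the elbow/gap curves in local
  optima (merging two planted blobs while splitting another); k-means++
  removes that failure mode. `k = n` is handled as the exact
  one-point-per-state solution.
- **Gap statistic** draws references uniformly over the data bounding box,
  reports `Gap(k) = mean_b log W_k(ref) - log W_k(data)` with
  `SE = sd * sqrt(1 + 1/B)`, and recommends both the argmax (the "higher
  the gap" reading) and the Tibshirani one-SE rule.
- **Transition pooling** excludes subject-boundary pairs by default
  (statistically correct); `include` reproduces plain concatenation with
  its "false transitions".
- **Empirical p-values** use the add-one estimator
  `(1 + #extreme) / (n_perm + 1)` and are never zero; two-sided p doubles
  the smaller tail, capped at 1.

## The entropy statistic and the three nulls

The topography matrix stacks, per state, the fraction of that state's
avalanches recruiting each region. Its concatenation `x` (length
`M = N x K`) yields `H(x) = -sum x_j ln x_j` in nats, with `0 ln 0 = 0` and
*no* renormalisation: H is a structure statistic, zero when recruitment is
deterministic (all fractions 0 or 1) and large when fractions are graded.
The concatenation order is irrelevant (the sum is order-invariant).

- **Null 1 — label shuffle** permutes state labels across avalanches
  (preserving state sizes) and recomputes topographies. Structured states
  concentrate fractions near 0/1, so the observed H falls far *below* the
  null and `p_low` is the headline. The per-(state, region) two-sided map
  at alpha = 0.05 flags regions recruited above (+1) or below (-1) chance.
- **Null 2 — sequence shuffle** permutes the within-subject chronological
  order of labels and recomputes the pooled transition matrix, giving a
  two-sided empirical p per transition cell (one-sided available) at
  alpha = 0.05, plus cross-subject consistency tallies.
- **Null 3 — region shuffle** permutes region positions *within each
  pattern* (preserving each pattern's size, destroying cross-pattern
  region identity) and re-runs the entire embedding + clustering per
  permutation, at alpha = 0.2 for the per-cell map. Because it re-embeds
  every permutation, its default is 99-999 permutations; 10000 is a flag
  away at proportional cost. Cluster identities are arbitrary across
  permutations, so per-cell comparisons order states by size first.

**A note on the direction of null 3.** For the concatenated-entropy
statistic, shuffled-and-reclustered data spread each state's recruitment
mass almost evenly over all regions, and `-x ln x` summed over a row of
fixed total mass is *maximised* by exactly that even spread. On planted
cohorts the observed entropy therefore lands far below the region-shuffle
null — the same side as null 1 — and the extreme lower tail, not the upper
tail, is what signals structure. Both tails are always reported. An upper
tail (`p_high`) can only become the signal when the original clusters have
graded mid-range fractions while the shuffled runs collapse into extreme
ones (for instance under heavy-tailed avalanche sizes, where shuffled
patterns cluster by size into near-empty and near-full topographies); the
generator's narrow planted size distribution is not in that regime. The
type-I calibration of `p_high` under region-exchangeable data is unaffected
by this and is tested.

## Problem sizes used in tests and the acceptance script

The full study conditions (18 subjects x 90 regions, ~3600 avalanches,
~1900 unique patterns) run end to end in a few minutes on one core and are
used for the recovery, transition and sparsity checks. Null-model
calibration uses 100 replicates of 199 permutations on small instances
(40-80 patterns over 12-15 regions), the scale at which the full-pipeline
region-shuffle null remains tractable; calibration depends on
exchangeability, not on instance size. Model-selection and trajectory
checks use 280-420 points. These sizes are the package's own choices for a
tight develop-test loop and scale linearly (nulls) or cubically (embedding)
if enlarged.

## Known limitations

- The embedding is dense O(U^2) in memory and O(U^3) in time; no landmark
  compression is provided, so U beyond ~10^4 unique patterns is
  impractical.
- The gap-statistic argmax can prefer k+1 when clusters are only marginally
  separated; the Tibshirani rule is reported alongside for that reason.
- Topographies are computed over all avalanche occurrences by default
  (`unique-only` is a flag-level decision left to the caller by passing
  deduplicated patterns), which weights recurrent patterns by their
  frequency.
- The region-shuffle null inherits the k-means seed; a pathological seed
  could in principle bias all permutations the same way, which the
  calibration test guards against empirically.
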