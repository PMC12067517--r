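# avstates

Brain activity at rest is intermittent: region-level neural recordings
(e.g., source-reconstructed MEG on the 90-region AAL atlas) spend most
samples in low-amplitude fluctuations, interrupted by brief large
coordinated excursions — *neuronal avalanches*. `avstates` analyses
large-scale brain dynamics through those events alone. It is written for
researchers who have region × time matrices in hand and want to know
whether the avalanches they contain organise into a small set of recurrent
brain states with non-random temporal structure.

## The method

1. **Avalanche patterns.** Each region is z-scored (population SD) and
   binarised at a strict threshold, |z| > 3. An avalanche runs from the
   first sample with any region above threshold to the next fully silent
   sample; it is summarised as a binary vector over the N regions recruited
   at any point during the event (the spatial OR, internal timing
   discarded).
2. **Diffusion embedding of the unique patterns.** PCA to 5 components;
   cosine distances d(i,j) = 1 − cos(xᵢ, xⱼ); adaptive kernel
   K(i,j) = ½[exp(−(d/ε₅(i))^α) + exp(−(d/ε₅(j))^α)] with ε₅ the distance
   to the 5th nearest neighbour and α = 1; row-normalisation into a
   diffusion operator P; diffusion time t at the knee of the von Neumann
   entropy of P^t; potential distances ‖log P^t[i,·] − log P^t[j,·]‖₂;
   metric MDS into 3-D. A PCA-only embedding is exposed through the same
   interface as the benchmark.
3. **States.** Seeded k-means++ (k = 7 by default) on the embedding, with
   elbow, silhouette and gap-statistic diagnostics for k; per-state
   topographies ξ (fraction of the state's avalanches recruiting each
   region).
4. **Dynamics.** Per-subject and pooled K × K transition matrices over the
   chronological avalanche labels (subject boundaries excluded by default).
5. **Validation.** Shannon entropy H(x) = −Σ xⱼ ln xⱼ over the concatenated
   topography vector against three permutation nulls: shuffled cluster
   labels, shuffled label sequences, and shuffled region identities within
   each pattern (the last re-runs the whole embedding per permutation).

The study's real recordings are not redistributable, so the package ships a
synthetic-data generator (`simulate_cohort()`) that plants known state
topographies and a Markov transition chain in realistic dimensions
(18 subjects × 90 regions × 6 min at 256 Hz, avalanches in <5% of samples),
giving every stage a ground truth.

## Worked example

```r
library(avstates)

cohort  <- simulate_cohort(sim_params(seed = 42))       # 18 planted subjects
pooled  <- pool_patterns(lapply(cohort$signals, detect_subject))
uq      <- unique_patterns(pooled)
emb     <- phate_embed(uq$patterns)                     # diffusion embedding
states  <- kmeans_states(emb$coords, k = 7, seed = 1)
labels  <- propagate_labels(states$labels, uq$index)

mclust::adjustedRandIndex(labels, unlist(cohort$truth$state_sequence))
#> [1] 1

topo <- cluster_topographies(pooled$patterns, labels, 7)
match_clusterings(topo, cohort$truth$topographies)$avg_max_correlation
#> [1] 0.9997067

ctm <- pooled_transition_matrix(split_sequences(labels, pooled$subject_ids), 7)
mean(diag(ctm$probs))   # self-transitions dominate, as planted
#> [1] 0.2316607
```

On this cohort the pipeline detects 3586 avalanches (1885 unique patterns;
subject 1 spends 4.0% of samples in avalanches), recovers the planted state
of every avalanche (adjusted Rand index 1), matches the planted topographies
at average maximum correlation 0.9997, and reproduces the planted chain's
dominant diagonal. `null_label_shuffle()` puts the observed topography
entropy below all permutations (p = 1e-3 at 999 permutations), and
`null_sequence_shuffle()` flags the planted self-transitions above chance.

The same steps as a narrated workflow live in `analysis/01_simulate.R` …
`analysis/06_sensitivity.R`, each writing tables under `results/`.

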