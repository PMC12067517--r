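#!/usr/bin/env Rscript
# Sensitivity analyses: robustness of the clustering to the binarization
# threshold, the kNN-distance diagnostic for the alpha-decay kernel, the
# PCA explained-variance curve, and the entropy comparison across
# labelings (diffusion embedding vs PCA-only vs planted).

library(avstates)

SEED <- 20260922L
cohort <- simulate_cohort(sim_params(seed = SEED))

# threshold scan (full pipeline per threshold; correlations vs threshold 3)
scan <- suppressWarnings(threshold_sensitivity_scan(
  cohort$signals, thresholds = c(3, 3.25, 3.5, 4, 4.5), k = 7,
  params = embedding_params(), seed = 13))
print(scan, row.names = FALSE)
utils::write.table(scan, "results/threshold_scan.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

pooled <- pool_patterns(lapply(cohort$signals, detect_subject))
uq <- unique_patterns(pooled)
emb <- phate_embed(uq$patterns)

# explained-variance curve (component-count diagnostic)
ev <- cumsum(emb$explained_variance_ratio)
cat(sprintf("cumulative explained variance: 1 PC %.3f, 5 PCs %.3f, 10 PCs %.3f\n",
            ev[1], ev[5], ev[10]))
utils::write.table(
  data.frame(component = seq_along(ev), cumulative_explained_variance = ev),
  "results/explained_variance.tsv", sep = "\t", row.names = FALSE,
  quote = FALSE)

# kNN-distance curves (alpha-decay diagnostic)
knn_d <- knn_distance_curves(emb$cosine_distances, k_max = 10)
cat(sprintf("median distance to 5th neighbour: %.3g (max %.3g)\n",
            median(knn_d[, 5]), max(knn_d[, 5])))

# entropy comparison across labelings
labels <- propagate_labels(kmeans_states(emb$coords, 7, seed = 13)$labels,
                           uq$index)
lab_pca <- propagate_labels(
  kmeans_states(pca_embed(uq$patterns)$coords, 7, seed = 13)$labels,
  uq$index)
tab <- method_entropy_comparison(
  list(diffusion = labels, pca_only = lab_pca,
       planted = unlist(cohort$truth$state_sequence)),
  pooled$patterns)
print(tab, row.names = FALSE)
utils::write.table(tab, "results/entropy_comparison.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

# cross-method topography matching (average max correlation)
topo_d <- cluster_topographies(pooled$patterns, labels, 7)
topo_p <- cluster_topographies(pooled$patterns, lab_pca, 7)
cat(sprintf("diffusion vs PCA-only topographies: average max correlation %.3f\n",
            match_clusterings(topo_d, topo_p)$avg_max_correlation))
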