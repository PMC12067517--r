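# Permutation null models and the Shannon-entropy statistic.
#
# Null 1 shuffles cluster labels across patterns (topography structure);
# null 2 shuffles the chronological order of avalanche labels (transition
# structure); null 3 shuffles region identities within each pattern and
# re-runs the whole embedding + clustering (embedding structure).
# Empirical p-values use the add-one estimator and are never 0.

#' Shannon entropy of a topography matrix
#'
#' Concatenates the `Nc x N` recruitment-fraction matrix into a vector of
#' length `M = Nc * N` and computes `H = -sum_j x_j * ln(x_j)` (nats), with
#' `0 * ln 0 = 0`. The vector is *not* renormalised to sum to one: H is a
#' structure statistic — it is 0 when every entry is 0 or 1 (perfectly
#' deterministic recruitment) and grows with graded, disordered recruitment.
#'
#' @param fractions matrix (or vector) of recruitment fractions in `[0, 1]`.
#' @return list with `H` (nats) and `M` (vector length).
#' @export
cluster_entropy <- function(fractions) {
  x <- as.numeric(fractions)
  if (anyNA(x) || any(x < 0) || any(x > 1)) {
    stop("entropy input must lie in [0, 1]", call. = FALSE)
  }
  pos <- x > 0
  list(H = -sum(x[pos] * log(x[pos])), M = length(x))
}

# add-one empirical tail probabilities of `obs` within `null_values`
tail_p <- function(obs, null_values) {
  n <- length(null_values)
  list(p_low = (1 + sum(null_values <= obs)) / (n + 1),
       p_high = (1 + sum(null_values >= obs)) / (n + 1))
}

# two-sided p by doubling the smaller add-one tail, capped at 1
two_sided_p <- function(obs, null_values) {
  p <- tail_p(obs, null_values)
  min(1, 2 * min(p$p_low, p$p_high))
}

#' Null model 1: cluster-label shuffle
#'
#' Each permutation reassigns the state labels across avalanche patterns
#' (preserving cluster sizes), recomputes the topographies and their entropy.
#' Structured clustering concentrates recruitment fractions near 0/1, so the
#' observed entropy is expected *below* the null (`p_low`). A per-(state,
#' region) trit map flags recruitment above (+1) or below (-1) chance at
#' `alpha`, two-sided.
#'
#' @param patterns `n x N` binary pattern matrix (all occurrences).
#' @param labels state label per pattern.
#' @param n_perm number of permutations (the full analysis uses 10000).
#' @param seed integer seed.
#' @param alpha significance level for the map.
#' @param n_states K.
#' @return list with `observed` (entropy), `null_values`, `p_low`, `p_high`,
#'   `n_perm`, `seed`, and `significance_map` (`K x N` in {-1, 0, +1}).
#' @export
null_label_shuffle <- function(patterns, labels, n_perm = 10000, seed = 29L,
                               alpha = 0.05, n_states = max(labels)) {
  assert_matrix(patterns, "pattern matrix")
  stopifnot(length(labels) == nrow(patterns))
  if (n_perm < 100) warning("n_perm < 100 gives unstable p-values")
  topo_obs <- cluster_topographies(patterns, labels, n_states)
  H_obs <- cluster_entropy(topo_obs$fractions)$H
  K <- n_states; N <- ncol(patterns)
  H_null <- numeric(n_perm)
  ge <- le <- matrix(0L, K, N)
  null_mean <- matrix(0, K, N)
  with_rng(seed, {
    for (b in seq_len(n_perm)) {
      lab_b <- sample(labels)
      topo_b <- cluster_topographies(patterns, lab_b, n_states)$fractions
      H_null[b] <- cluster_entropy(topo_b)$H
      ge <- ge + (topo_b >= topo_obs$fractions)
      le <- le + (topo_b <= topo_obs$fractions)
      null_mean <- null_mean + topo_b
    }
  })
  null_mean <- null_mean / n_perm
  p_hi_cell <- (1 + ge) / (n_perm + 1)
  p_lo_cell <- (1 + le) / (n_perm + 1)
  p_cell <- pmin(2 * pmin(p_hi_cell, p_lo_cell), 1)
  sig <- matrix(0L, K, N, dimnames = dimnames(topo_obs$fractions))
  sig[p_cell <= alpha & topo_obs$fractions > null_mean] <- 1L
  sig[p_cell <= alpha & topo_obs$fractions < null_mean] <- -1L
  p <- tail_p(H_obs, H_null)
  list(observed = H_obs, null_values = H_null, p_low = p$p_low,
       p_high = p$p_high, n_perm = as.integer(n_perm), seed = as.integer(seed),
       alpha = alpha, significance_map = sig, cell_p = p_cell)
}

#' Null model 2: sequence shuffle for transition structure
#'
#' Each permutation shuffles the chronological order of the state labels
#' within each subject (preserving label counts; `pooled = TRUE` shuffles the
#' concatenated sequence instead), recomputes the pooled transition matrix,
#' and yields an empirical p-value per transition cell. Cells are flagged
#' above (+1) or below (-1) chance at `alpha`.
#'
#' @param sequences named list of per-subject label sequences.
#' @param n_states K.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param alpha significance level.
#' @param pooled shuffle across the concatenated sequence instead of within
#'   subjects.
#' @param two_sided logical; if `FALSE`, one-sided p-values (both tails
#'   reported, mask uses the smaller).
#' @param boundary_policy passed to [pooled_transition_matrix()].
#' @return list with `observed` (`transition_matrix`), `p` (`K x K`),
#'   `mask` (`K x K` in {-1, 0, +1}), `null_mean`, `n_perm`, `seed`.
#' @export
null_sequence_shuffle <- function(sequences, n_states = max(unlist(sequences)),
                                  n_perm = 10000, seed = 31L, alpha = 0.05,
                                  pooled = FALSE, two_sided = TRUE,
                                  boundary_policy = "exclude") {
  stopifnot(length(sequences) >= 1)
  obs <- pooled_transition_matrix(sequences, n_states, boundary_policy)
  K <- n_states
  ge <- le <- matrix(0L, K, K)
  null_mean <- matrix(0, K, K)
  with_rng(seed, {
    for (b in seq_len(n_perm)) {
      seq_b <- if (pooled) {
        flat <- sample(unlist(sequences, use.names = FALSE))
        list(flat)
      } else {
        lapply(sequences, sample)
      }
      p_b <- pooled_transition_matrix(seq_b, n_states, boundary_policy)$probs
      ge <- ge + (p_b >= obs$probs)
      le <- le + (p_b <= obs$probs)
      null_mean <- null_mean + p_b
    }
  })
  null_mean <- null_mean / n_perm
  p_hi <- (1 + ge) / (n_perm + 1)
  p_lo <- (1 + le) / (n_perm + 1)
  p <- if (two_sided) pmin(2 * pmin(p_hi, p_lo), 1) else pmin(p_hi, p_lo)
  mask <- matrix(0L, K, K, dimnames = dimnames(obs$probs))
  mask[p <= alpha & obs$probs > null_mean] <- 1L
  mask[p <= alpha & obs$probs < null_mean] <- -1L
  dimnames(p) <- dimnames(obs$probs)
  list(observed = obs, p = p, mask = mask, null_mean = null_mean,
       p_high = p_hi, p_low = p_lo,
       n_perm = as.integer(n_perm), seed = as.integer(seed), alpha = alpha)
}

#' Null model 3: region shuffle for embedding structure
#'
#' Each permutation independently permutes the region positions within every
#' avalanche pattern (preserving each pattern's active count while destroying
#' cross-pattern region identity), then re-runs the full embedding and
#' k-means pipeline and recomputes the topography entropy. Structure in the
#' original data lets clustering carve patterns into coherent states whose
#' recruitment fractions are graded across many regions, so the observed
#' entropy is expected *above* the null (`p_high`): shuffled patterns have no
#' shared structure and clustering collapses recruitment towards uniform
#' marginal rates concentrated near 0.
#'
#' For the per-(state, region) map, states of each run are ordered by cluster
#' size before cellwise comparison (cluster identities are arbitrary across
#' permutations); significance level defaults to `alpha = 0.2`.
#'
#' @param patterns `n x N` binary pattern matrix (all occurrences).
#' @param k number of states.
#' @param params an [embedding_params()] object.
#' @param n_perm number of permutations; defaults to 99 because every
#'   permutation re-runs the embedding (pass 10000 to match the full
#'   analysis at proportional cost).
#' @param seed integer seed.
#' @param alpha significance level for the map.
#' @param cluster_seed seed for the k-means stage.
#' @param n_init k-means restarts for every (observed and permuted) run.
#' @return list with `observed`, `null_values`, `p_low`, `p_high`,
#'   `significance_map`, `n_perm`, `seed`.
#' @export
null_region_shuffle <- function(patterns, k = 7, params = embedding_params(),
                                n_perm = 99, seed = 37L, alpha = 0.2,
                                cluster_seed = 13L, n_init = 10) {
  assert_matrix(patterns, "pattern matrix")
  n <- nrow(patterns); N <- ncol(patterns)
  run_pipeline_once <- function(pat) {
    key <- apply(pat, 1, paste, collapse = "")
    first <- !duplicated(key)
    uq <- pat[first, , drop = FALSE]
    idx <- match(key, key[first])
    emb <- phate_embed(uq, params, keep_intermediates = FALSE)
    sm <- kmeans_states(emb$coords, k = k, seed = cluster_seed,
                        n_init = n_init)
    labels <- propagate_labels(sm$labels, idx)
    topo <- cluster_topographies(pat, labels, n_states = k)
    ord <- order(topo$cluster_sizes, decreasing = TRUE)
    list(H = cluster_entropy(topo$fractions)$H,
         fractions = topo$fractions[ord, , drop = FALSE])
  }
  obs <- run_pipeline_once(patterns)
  H_null <- numeric(n_perm)
  ge <- le <- matrix(0L, k, N)
  null_mean <- matrix(0, k, N)
  with_rng(seed, {
    for (b in seq_len(n_perm)) {
      pat_b <- patterns
      for (i in seq_len(n)) pat_b[i, ] <- patterns[i, sample.int(N)]
      res_b <- run_pipeline_once(pat_b)
      H_null[b] <- res_b$H
      ge <- ge + (res_b$fractions >= obs$fractions)
      le <- le + (res_b$fractions <= obs$fractions)
      null_mean <- null_mean + res_b$fractions
    }
  })
  null_mean <- null_mean / n_perm
  p_hi_cell <- (1 + ge) / (n_perm + 1)
  p_lo_cell <- (1 + le) / (n_perm + 1)
  p_cell <- pmin(2 * pmin(p_hi_cell, p_lo_cell), 1)
  sig <- matrix(0L, k, N)
  sig[p_cell <= alpha & obs$fractions > null_mean] <- 1L
  sig[p_cell <= alpha & obs$fractions < null_mean] <- -1L
  p <- tail_p(obs$H, H_null)
  list(observed = obs$H, null_values = H_null, p_low = p$p_low,
       p_high = p$p_high, n_perm = as.integer(n_perm),
       seed = as.integer(seed), alpha = alpha, significance_map = sig)
}

#' Cross-subject transition consistency
#'
#' Tallies, per transition cell, how many subjects flag it significant in
#' the same direction.
#'
#' @param masks list of per-subject `K x K` trit masks (from
#'   [null_sequence_shuffle()]).
#' @return list with `above` and `below` count matrices.
#' @export
transition_consistency <- function(masks) {
  stopifnot(length(masks) >= 1)
  K <- nrow(masks[[1]])
  stopifnot(all(vapply(masks, function(m) all(dim(m) == K), TRUE)))
  list(above = Reduce(`+`, lapply(masks, function(m) (m == 1L) * 1L)),
       below = Reduce(`+`, lapply(masks, function(m) (m == -1L) * 1L)))
}

#' Entropy comparison across labelings
#'
#' Computes the topography entropy for each candidate labeling of the same
#' pattern set (e.g., alternative clustering methods). Higher entropy
#' indicates more complex — potentially noisier — cluster structure.
#'
#' @param labelings named list of label vectors (each covering all patterns).
#' @param patterns `n x N` binary pattern matrix.
#' @return data.frame with `name`, `k`, `entropy`.
#' @export
method_entropy_comparison <- function(labelings, patterns) {
  stopifnot(length(labelings) >= 1, !is.null(names(labelings)))
  rows <- lapply(names(labelings), function(nm) {
    lab <- labelings[[nm]]
    stopifnot(length(lab) == nrow(patterns))
    topo <- cluster_topographies(patterns, lab)
    data.frame(name = nm, k = max(lab),
               entropy = cluster_entropy(topo$fractions)$H,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
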