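# State characterisation and dynamics: cluster topographies, label
# propagation, per-subject and pooled transition matrices, inter-subject
# variability, cross-clustering matching, and the threshold sensitivity scan.

#' Cluster topographies (region recruitment per state)
#'
#' For each state, counts how often each region is active in the avalanche
#' patterns assigned to it, and expresses recruitment as a fraction of the
#' cluster size.
#'
#' @param patterns `n x N` binary pattern matrix (all avalanche occurrences).
#' @param labels integer state label per pattern (1..K).
#' @param n_states K; defaults to `max(labels)`.
#' @return object of class `topography_matrix`: `fractions` and `counts`
#'   (`K x N`), `cluster_sizes`.
#' @export
cluster_topographies <- function(patterns, labels, n_states = max(labels)) {
  assert_matrix(patterns, "pattern matrix")
  stopifnot(length(labels) == nrow(patterns), all(labels >= 1),
            all(labels <= n_states))
  f <- factor(labels, levels = seq_len(n_states))
  sizes <- as.integer(table(f))
  if (any(sizes == 0)) {
    stop("empty cluster: state ", which(sizes == 0)[1],
         " has no patterns", call. = FALSE)
  }
  counts <- rowsum(patterns, f)
  fractions <- counts / sizes
  dimnames(counts) <- dimnames(fractions) <-
    list(paste0("state_", seq_len(n_states)), colnames(patterns))
  structure(list(fractions = fractions, counts = counts,
                 cluster_sizes = sizes),
            class = "topography_matrix")
}

#' Propagate unique-pattern labels to every avalanche
#'
#' @param unique_labels state label per unique pattern.
#' @param index occurrence index from [unique_patterns()].
#' @return integer label per avalanche occurrence, chronological order.
#' @export
propagate_labels <- function(unique_labels, index) {
  if (any(index < 1) || any(index > length(unique_labels))) {
    stop("occurrence index out of range", call. = FALSE)
  }
  as.integer(unique_labels[index])
}

#' Split a pooled label vector into per-subject sequences
#'
#' @param labels per-avalanche labels (pooled, chronological within subject).
#' @param subject_ids matching subject id per avalanche.
#' @return named list of integer label sequences, one per subject, in first
#'   appearance order.
#' @export
split_sequences <- function(labels, subject_ids) {
  stopifnot(length(labels) == length(subject_ids))
  ids <- unique(subject_ids)
  out <- lapply(ids, function(id) as.integer(labels[subject_ids == id]))
  names(out) <- ids
  out
}

#' Transition matrix of a state-label sequence
#'
#' Counts consecutive pairs and row-normalises. Rows whose state never
#' occurs as a transition source stay all-zero and are flagged.
#'
#' @param label_sequence integer sequence (1..K).
#' @param n_states K.
#' @param subject_id label stored on the result.
#' @return object of class `transition_matrix`: `probs`, `counts` (`K x K`),
#'   `zero_rows` (logical), `subject_id`.
#' @export
transition_matrix <- function(label_sequence, n_states = max(label_sequence),
                              subject_id = "pooled") {
  counts <- matrix(0L, n_states, n_states)
  n <- length(label_sequence)
  if (n >= 2) {
    from <- factor(label_sequence[-n], levels = seq_len(n_states))
    to <- factor(label_sequence[-1], levels = seq_len(n_states))
    counts <- unclass(table(from, to))
  }
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, 1, rs)
  dimnames(counts) <- dimnames(probs) <-
    list(paste0("state_", seq_len(n_states)), paste0("state_", seq_len(n_states)))
  structure(list(probs = probs, counts = counts, zero_rows = rs == 0,
                 subject_id = subject_id),
            class = "transition_matrix")
}

#' Pooled transition matrix across subjects
#'
#' `exclude` (default) sums within-subject transition counts only — no pair
#' spans a subject boundary. `include` concatenates the sequences first,
#' adding one boundary ("false") transition per junction.
#'
#' @param sequences named list of per-subject label sequences.
#' @param n_states K.
#' @param boundary_policy `"exclude"` or `"include"`.
#' @return a `transition_matrix` with `subject_id = "pooled"`.
#' @export
pooled_transition_matrix <- function(sequences,
                                     n_states = max(unlist(sequences)),
                                     boundary_policy = c("exclude", "include")) {
  boundary_policy <- match.arg(boundary_policy)
  stopifnot(length(sequences) >= 1)
  if (boundary_policy == "include") {
    return(transition_matrix(unlist(sequences, use.names = FALSE), n_states))
  }
  counts <- Reduce(`+`, lapply(sequences, function(s) {
    transition_matrix(s, n_states)$counts
  }))
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, 1, rs)
  structure(list(probs = probs, counts = counts, zero_rows = rs == 0,
                 subject_id = "pooled"),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %s, K = %d, %d transitions\n",
              x$subject_id, nrow(x$probs), sum(x$counts)))
  print(round(x$probs, 3))
  invisible(x)
}

#' Inter-subject transition variability
#'
#' Cellwise mean, population SD and coefficient of variation of transition
#' probabilities across subjects. Zero-flagged rows are excluded from the
#' sample of the corresponding cells.
#'
#' @param tms list of per-subject `transition_matrix` objects (same K).
#' @return list with `mean`, `sd`, `cv` (`K x K`; `cv` is `NA` where the mean
#'   is 0) and `n` (contributing subjects per cell).
#' @export
transition_variability <- function(tms) {
  stopifnot(length(tms) >= 1, all(vapply(tms, inherits, TRUE, "transition_matrix")))
  K <- nrow(tms[[1]]$probs)
  arr <- vapply(tms, function(tm) {
    p <- tm$probs
    p[tm$zero_rows, ] <- NA_real_
    p
  }, matrix(0, K, K))
  n <- apply(!is.na(arr), c(1, 2), sum)
  mu <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  sdv <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    sqrt(mean((v - mean(v))^2))
  })
  cv <- ifelse(!is.na(mu) & mu > 0, sdv / mu, NA_real_)
  list(mean = mu, sd = sdv, cv = cv, n = n)
}

#' Match two clusterings by topography correlation
#'
#' Pearson correlation between every row pair of two topography matrices,
#' the per-row maximum (directional, A over B), its average, and a greedy
#' one-to-one matching for state alignment.
#'
#' @param topoA,topoB `topography_matrix` objects (or plain matrices) over
#'   the same regions.
#' @return list with `correlation` (`KA x KB`), `row_max`, `avg_max_correlation`,
#'   and `matching` (data.frame `a`, `b`, `correlation`, greedy one-to-one).
#' @export
match_clusterings <- function(topoA, topoB) {
  A <- if (inherits(topoA, "topography_matrix")) topoA$fractions else as.matrix(topoA)
  B <- if (inherits(topoB, "topography_matrix")) topoB$fractions else as.matrix(topoB)
  stopifnot(ncol(A) == ncol(B))
  C <- suppressWarnings(stats::cor(t(A), t(B)))
  if (anyNA(C)) {
    warning("constant topography row(s): undefined correlations set to 0")
    C[is.na(C)] <- 0
  }
  row_max <- apply(C, 1, max)
  # greedy one-to-one matching by descending correlation
  Cw <- C
  m <- min(nrow(C), ncol(C))
  pairs <- data.frame(a = integer(m), b = integer(m), correlation = numeric(m))
  for (i in seq_len(m)) {
    ij <- arrayInd(which.max(Cw), dim(Cw))
    pairs$a[i] <- ij[1]; pairs$b[i] <- ij[2]
    pairs$correlation[i] <- C[ij[1], ij[2]]
    Cw[ij[1], ] <- -Inf
    Cw[, ij[2]] <- -Inf
  }
  list(correlation = C, row_max = row_max,
       avg_max_correlation = mean(row_max),
       matching = pairs[order(pairs$a), ])
}

#' Threshold sensitivity scan
#'
#' Re-runs the full pipeline (detection, unique patterns, embedding,
#' k-means, topographies) at each binarization threshold and reports the
#' cluster entropy plus the average-max topography correlation against the
#' reference threshold's states.
#'
#' @param signals list of [signal_set()] objects.
#' @param thresholds numeric vector of thresholds to scan.
#' @param reference_threshold threshold whose topographies anchor the
#'   correlations (default 3).
#' @param k number of states.
#' @param params an [embedding_params()] object.
#' @param seed clustering seed.
#' @param mode binarization mode.
#' @return data.frame with one row per threshold: `threshold`,
#'   `n_avalanches`, `n_unique`, `entropy`, `correlation_with_reference`
#'   (`NA` where no avalanches survive).
#' @export
threshold_sensitivity_scan <- function(signals, thresholds,
                                       reference_threshold = 3, k = 7,
                                       params = embedding_params(),
                                       seed = 13L, mode = "absolute") {
  run_one <- function(thr) {
    seqs <- lapply(signals, detect_subject, threshold = thr, mode = mode)
    pooled <- pool_patterns(seqs)
    if (nrow(pooled$patterns) < max(k, params$knn + 2)) return(NULL)
    uq <- unique_patterns(pooled)
    emb <- phate_embed(uq$patterns, params, keep_intermediates = FALSE)
    sm <- kmeans_states(emb$coords, k = k, seed = seed)
    labels <- propagate_labels(sm$labels, uq$index)
    topo <- cluster_topographies(pooled$patterns, labels, n_states = k)
    list(n_avalanches = nrow(pooled$patterns), n_unique = nrow(uq$patterns),
         topo = topo, entropy = cluster_entropy(topo$fractions)$H)
  }
  ref <- run_one(reference_threshold)
  if (is.null(ref)) stop("no avalanches at the reference threshold", call. = FALSE)
  rows <- lapply(thresholds, function(thr) {
    res <- tryCatch(run_one(thr), error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(threshold = thr, n_avalanches = 0L, n_unique = 0L,
                        entropy = NA_real_,
                        correlation_with_reference = NA_real_))
    }
    data.frame(threshold = thr, n_avalanches = res$n_avalanches,
               n_unique = res$n_unique, entropy = res$entropy,
               correlation_with_reference =
                 match_clusterings(res$topo, ref$topo)$avg_max_correlation)
  })
  do.call(rbind, rows)
}
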