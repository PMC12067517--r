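# Shared fixtures, built in code at test time.

# Small planted cohort: 4 subjects, 30 regions, 4 states, ~60 events each.
small_cohort <- function(seed = 5, ...) {
  simulate_cohort(sim_params(
    n_regions = 30, n_states = 4, regions_per_state = 6, duration = 60,
    n_subjects = 4, event_rate = 1, event_duration_mean = 10,
    topography_overlap = 0.2, seed = seed, ...))
}

# Detection output pooled across a cohort's subjects.
cohort_patterns <- function(cohort, threshold = 3, mode = "absolute") {
  pool_patterns(lapply(cohort$signals, detect_subject,
                       threshold = threshold, mode = mode))
}

# Random sparse binary patterns with exchangeable regions.
random_patterns <- function(n, n_regions, size, seed) {
  withr::with_seed(seed, {
    pat <- matrix(0L, n, n_regions)
    for (i in seq_len(n)) pat[i, sample.int(n_regions, size)] <- 1L
    pat
  })
}

# Gaussian blobs with guaranteed center separation.
separated_blobs <- function(seed, k = 7, per = 40, d = 3, sep = 8, sd = 0.5) {
  withr::with_seed(seed, {
    repeat {
      centers <- matrix(stats::runif(k * d, -10, 10), k, d)
      if (min(stats::dist(centers)) > sep) break
    }
    centers[rep(seq_len(k), each = per), ] +
      matrix(stats::rnorm(k * per * d, sd = sd), k * per, d)
  })
}

# Noisy 1-D trajectory (quarter-circle arc lifted into 10 dimensions).
trajectory_data <- function(seed, n = 200, noise = 0.03) {
  withr::with_seed(seed, {
    tt <- sort(stats::runif(n))
    ang <- tt * pi / 2
    lift <- matrix(stats::runif(2 * 10, 0.5, 1.5), 2, 10)
    X <- cbind(cos(ang), sin(ang)) %*% lift + 2 +
      matrix(stats::rnorm(n * 10, sd = noise), n, 10)
    list(t = tt, X = X)
  })
}

# Align recovered state labels to planted states by greedy topography matching.
align_to_planted <- function(labels, patterns, planted_topo) {
  k <- nrow(planted_topo)
  topo <- cluster_topographies(patterns, labels, k)
  m <- match_clusterings(topo$fractions, planted_topo)$matching
  perm <- integer(k)
  perm[m$a] <- m$b
  perm[labels]
}
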