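test_that("PCA reduction reproduces a covariance-eigendecomposition oracle", {
  # rank-1 data: first component explains everything
  X1 <- outer(1:20, c(1, 2, 3))
  p1 <- pca_reduce(X1 + 0, 1)
  expect_equal(p1$explained_variance_ratio[1], 1, tolerance = 1e-10)

  X <- withr::with_seed(7, matrix(stats::rnorm(500), 50, 10))
  p <- pca_reduce(X, 4)
  expect_equal(sum(p$explained_variance_ratio), 1, tolerance = 1e-10)
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))

  # oracle: eigendecomposition of the covariance matrix
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  scores_oracle <- Xc %*% ev$vectors[, 1:4]
  for (j in 1:4) {
    expect_equal(abs(stats::cor(p$scores[, j], scores_oracle[, j])), 1,
                 tolerance = 1e-8)
    expect_equal(sort(abs(p$scores[, j])), sort(abs(scores_oracle[, j])),
                 tolerance = 1e-8)
  }

  expect_warning(pca_reduce(outer(1:20, c(1, 2, 3)) + 0, 3), "rank")
})

test_that("cosine distances match the closed form and a brute-force loop", {
  x <- rbind(c(1, 0), c(0, 2), c(-3, 0), c(2, 0))
  D <- cosine_distance_matrix(x)
  expect_equal(D[1, 4], 0)           # parallel
  expect_equal(D[1, 2], 1)           # orthogonal
  expect_equal(D[1, 3], 2)           # antiparallel
  expect_equal(diag(D), rep(0, 4))

  X <- withr::with_seed(3, matrix(stats::rnorm(100), 20, 5))
  D2 <- cosine_distance_matrix(X)
  for (i in 1:20) for (j in 1:20) {
    expect_equal(D2[i, j],
                 1 - sum(X[i, ] * X[j, ]) /
                   sqrt(sum(X[i, ]^2) * sum(X[j, ]^2)),
                 tolerance = 1e-12)
  }
  expect_error(cosine_distance_matrix(rbind(c(0, 0), c(1, 1))), "zero row")
})

test_that("alpha-decay kernel matches the literal formula", {
  # closed form: at d = eps_k for both points, K = exp(-1)
  D <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
  K <- alpha_decay_kernel(D, knn = 1, alpha = 1)
  expect_equal(K[1, 2], exp(-1))
  expect_equal(diag(K), rep(1, 3))

  X <- withr::with_seed(11, matrix(stats::rnorm(50), 10, 5))
  D2 <- cosine_distance_matrix(X)
  K2 <- alpha_decay_kernel(D2, knn = 3, alpha = 2)
  # oracle: literal double loop over the formula
  eps <- vapply(1:10, function(i) sort(D2[i, -i])[3], numeric(1))
  for (i in 1:10) for (j in 1:10) {
    if (i == j) next
    expect_equal(K2[i, j],
                 (exp(-(D2[i, j] / eps[i])^2) + exp(-(D2[i, j] / eps[j])^2)) / 2,
                 tolerance = 1e-12)
  }
  expect_true(isSymmetric(K2))
  expect_true(all(K2 > 0 & K2 <= 1))

  # duplicate points give zero bandwidth
  Ddup <- as.matrix(stats::dist(rbind(c(0, 0), c(0, 0), c(1, 1))))
  expect_error(alpha_decay_kernel(Ddup, knn = 1), "degenerate")
})

test_that("Markov normalization is row-stochastic and powers correctly", {
  K <- matrix(c(1, 1, 1, 1), 2)
  P <- markov_normalize(K)
  expect_equal(P, matrix(0.5, 2, 2))

  K2 <- withr::with_seed(5, matrix(stats::runif(64), 8, 8))
  P2 <- markov_normalize(K2)
  expect_equal(rowSums(P2), rep(1, 8), tolerance = 1e-12)
  # repeated matrix-vector products oracle for P^2, and stochasticity
  # under powering
  P2sq <- P2 %*% P2
  oracle <- vapply(1:8, function(i) as.numeric(P2 %*% (P2 %*% diag(8)[, i])),
                   numeric(8))
  expect_equal(P2sq, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  for (t in c(2, 5, 16)) {
    Pt <- avstates:::mat_power(P2, t)
    expect_equal(rowSums(Pt), rep(1, 8), tolerance = 1e-10)
  }
  expect_error(markov_normalize(rbind(c(0, 0), c(1, 1))), "zero row")
})

test_that("diffusion time selection is deterministic with a flat-curve fallback", {
  expect_warning(t1 <- select_diffusion_time(diag(5)), "flat")
  expect_equal(t1, 1L)

  # two well-separated blobs: VNE knee picked consistently
  X <- rbind(matrix(stats::rnorm(40, 0), 20, 2),
             matrix(stats::rnorm(40, 20), 20, 2))
  D <- as.matrix(stats::dist(X))
  K <- alpha_decay_kernel(D, 5, 1)
  P <- markov_normalize(K)
  ta <- select_diffusion_time(P, K = K)
  tb <- select_diffusion_time(P, K = K)
  expect_identical(ta, tb)
  expect_gte(ta, 1L)
  # knee agrees with a direct scan of the entropy curve
  vne <- avstates:::vne_curve(P, t_max = 100, K = K)
  expect_equal(ta, avstates:::knee_point(1:100, vne))
})

test_that("potential distances match a hand-computed 3-state operator", {
  P <- matrix(c(0.8, 0.1, 0.1,
                0.2, 0.6, 0.2,
                0.3, 0.3, 0.4), 3, byrow = TRUE)
  Dp <- potential_distances(P, 1)
  # oracle: literal formula on logs
  L <- log(P)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(Dp[i, j], sqrt(sum((L[i, ] - L[j, ])^2)), tolerance = 1e-10)
  }
  expect_equal(diag(Dp), rep(0, 3))

  # identical rows give zero distance
  P2 <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(potential_distances(P2, 3), matrix(0, 2, 2))

  # triangle inequality on sampled triples of a random operator
  P3 <- markov_normalize(withr::with_seed(9, matrix(stats::runif(400) + 0.01, 20, 20)))
  D3 <- potential_distances(P3, 2)
  trips <- withr::with_seed(10, replicate(50, sample.int(20, 3), simplify = FALSE))
  for (tr in trips) {
    expect_lte(D3[tr[1], tr[3]], D3[tr[1], tr[2]] + D3[tr[2], tr[3]] + 1e-10)
  }
})

test_that("metric MDS recovers realizable geometries and is deterministic", {
  # perfect square in 2-D
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  D <- as.matrix(stats::dist(sq))
  m <- mds_embed(D, 2, seed = 1)
  expect_equal(as.matrix(stats::dist(m$coords)), D, tolerance = 0.01,
               ignore_attr = TRUE)

  # exactly realizable distances give ~zero stress at full dimensionality
  X5 <- withr::with_seed(2, matrix(stats::rnorm(30), 6, 5))
  D5 <- as.matrix(stats::dist(X5))
  m5 <- mds_embed(D5, 5, seed = 1)
  expect_lt(m5$stress, 1e-8)

  m2a <- mds_embed(D, 2, seed = 7)
  m2b <- mds_embed(D, 2, seed = 7)
  expect_identical(m2a$coords, m2b$coords)
})

test_that("full embedding separates pattern families and respects permutation", {
  co <- small_cohort()
  pooled <- cohort_patterns(co)
  uq <- unique_patterns(pooled)
  emb <- suppressWarnings(phate_embed(uq$patterns))
  expect_true(all(is.finite(emb$coords)))
  expect_equal(nrow(emb$coords), nrow(uq$patterns))

  # between-family distances dominate within-family distances
  planted <- unlist(co$truth$state_sequence)
  uq_state <- planted[match(seq_len(nrow(uq$patterns)), uq$index)]
  D <- as.matrix(stats::dist(emb$coords))
  same <- outer(uq_state, uq_state, "==") & upper.tri(D)
  diff_fam <- (!outer(uq_state, uq_state, "==")) & upper.tri(D)
  q_within <- stats::quantile(D[same], 0.95)
  frac <- mean(D[diff_fam] > q_within)
  expect_gte(frac, 0.95)

  # operator rows remain stochastic at the selected power
  Pt <- avstates:::mat_power(emb$operator, emb$t)
  expect_equal(rowSums(Pt), rep(1, nrow(Pt)), tolerance = 1e-10)
})

test_that("embedding preserves a noisy 1-D trajectory on its first axis", {
  d <- trajectory_data(seed = 1)
  emb <- suppressWarnings(phate_embed(d$X, keep_intermediates = FALSE))
  rho <- stats::cor(d$t, emb$coords[, 1], method = "spearman")
  expect_gte(abs(rho), 0.9)
})
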