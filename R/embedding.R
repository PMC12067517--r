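# Diffusion-based dimensionality reduction of avalanche patterns:
# PCA -> cosine distances -> adaptive alpha-decay kNN kernel -> Markov
# normalization -> diffusion-time selection by von Neumann entropy knee ->
# potential distances -> metric MDS. A plain PCA path is exposed through the
# same interface for benchmarking.

#' Embedding parameters
#'
#' Defaults follow the pipeline's standard settings: 5 principal components,
#' cosine distances, 5 nearest neighbours, alpha-decay 1, 3 output
#' dimensions, diffusion time selected automatically at the knee of the von
#' Neumann entropy curve.
#'
#' @param n_pca number of principal components retained.
#' @param knn kernel bandwidth neighbour (k-th nearest, self excluded).
#' @param alpha decay exponent (>= 1).
#' @param n_dims output dimensionality.
#' @param t diffusion time: positive integer or `"auto"`.
#' @param t_max scan bound for automatic t selection.
#' @param mds_seed seed for the MDS stage (used only for degenerate
#'   initialisations; classical-MDS initialisation is deterministic).
#' @param mds_max_iter SMACOF iteration cap for the MDS stage.
#' @param potential `"log"` for potential distances (default) or `"diffused"`
#'   to embed the diffused input distances instead.
#' @return object of class `embedding_params`.
#' @export
embedding_params <- function(n_pca = 5, knn = 5, alpha = 1, n_dims = 3,
                             t = "auto", t_max = 100, mds_seed = 11L,
                             mds_max_iter = 200,
                             potential = c("log", "diffused")) {
  potential <- match.arg(potential)
  stopifnot(n_pca >= 1, knn >= 1, alpha >= 1, n_dims >= 1,
            identical(t, "auto") || (is.numeric(t) && t >= 1))
  structure(list(n_pca = as.integer(n_pca), knn = as.integer(knn),
                 alpha = alpha, n_dims = as.integer(n_dims), t = t,
                 t_max = as.integer(t_max), mds_seed = as.integer(mds_seed),
                 mds_max_iter = as.integer(mds_max_iter),
                 potential = potential),
            class = "embedding_params")
}

#' PCA reduction with explained variance
#'
#' Column-centred PCA via [stats::prcomp()]; components are ordered by
#' decreasing variance. If the matrix has rank below `n_components`, only
#' rank-many components are returned with a warning.
#'
#' @param X `U x N` numeric matrix.
#' @param n_components number of components requested.
#' @return list with `scores` (`U x C`), `explained_variance_ratio`
#'   (all components, sums to 1) and `n_components` actually returned.
#' @export
pca_reduce <- function(X, n_components) {
  assert_matrix(X, "pattern matrix")
  stopifnot(n_components >= 1, nrow(X) > n_components)
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  var_all <- p$sdev^2
  ratio <- var_all / sum(var_all)
  rank <- sum(p$sdev > p$sdev[1] * 1e-12)
  C <- min(n_components, rank)
  if (C < n_components) {
    warning("matrix rank ", rank, " < requested ", n_components,
            " components; returning ", C)
  }
  list(scores = p$x[, seq_len(C), drop = FALSE],
       explained_variance_ratio = ratio,
       n_components = C)
}

#' Pairwise cosine distances
#'
#' `d(i, j) = 1 - cos(x_i, x_j)`, symmetric with zero diagonal, in `[0, 2]`.
#'
#' @param scores `U x C` matrix with no zero rows.
#' @return `U x U` distance matrix.
#' @export
cosine_distance_matrix <- function(scores) {
  assert_matrix(scores, "scores")
  nrm <- sqrt(rowSums(scores^2))
  if (any(nrm < .Machine$double.eps)) {
    stop("zero row in scores: cosine distance undefined for row ",
         which(nrm < .Machine$double.eps)[1], call. = FALSE)
  }
  S <- tcrossprod(scores / nrm)
  S[S > 1] <- 1; S[S < -1] <- -1
  D <- 1 - S
  diag(D) <- 0
  (D + t(D)) / 2
}

#' Adaptive alpha-decay kernel
#'
#' Symmetrised kernel with per-point bandwidth equal to the distance to the
#' `knn`-th nearest neighbour (self excluded, ties broken by index order):
#' `K(i,j) = (exp(-(d_ij / eps_i)^alpha) + exp(-(d_ij / eps_j)^alpha)) / 2`.
#'
#' @param D distance matrix.
#' @param knn bandwidth neighbour.
#' @param alpha decay exponent.
#' @return symmetric affinity matrix with unit diagonal, entries in (0, 1].
#' @export
alpha_decay_kernel <- function(D, knn = 5, alpha = 1) {
  assert_matrix(D, "distance matrix")
  n <- nrow(D)
  stopifnot(ncol(D) == n, knn >= 1, knn <= n - 1, alpha >= 1)
  eps <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    sort(d, method = "radix")[knn]
  }, numeric(1))
  if (any(eps <= 0)) {
    stop("degenerate bandwidth: point ", which(eps <= 0)[1],
         " has its ", knn, "-th neighbour at distance 0 (duplicate points?)",
         call. = FALSE)
  }
  K <- (exp(-(D / eps)^alpha) + exp(-t(t(D) / eps)^alpha)) / 2
  diag(K) <- 1
  K
}

#' Row-normalise an affinity matrix into a diffusion operator
#'
#' @param K nonnegative affinity matrix with positive row sums.
#' @return row-stochastic matrix `P` with `P[i,j] = K[i,j] / sum_j K[i,j]`.
#' @export
markov_normalize <- function(K) {
  assert_matrix(K, "affinity matrix")
  if (any(K < 0)) stop("affinity matrix must be nonnegative", call. = FALSE)
  rs <- rowSums(K)
  if (any(rs <= 0)) {
    stop("zero row sum at row ", which(rs <= 0)[1], call. = FALSE)
  }
  K / rs
}

# von Neumann entropy curve of the diffusion operator over powers 1..t_max,
# computed from the eigenvalues of the symmetric conjugate
# A = D^{1/2} P D^{-1/2} (same spectrum as P, real eigenvalues).
vne_curve <- function(P, t_max = 100, K = NULL) {
  rs_sqrt <- if (is.null(K)) NULL else sqrt(rowSums(K))
  A <- if (is.null(K)) {
    # without the kernel, fall back to direct symmetrisation of P
    (P + t(P)) / 2
  } else {
    (K / rs_sqrt) / rep(rs_sqrt, each = nrow(K))
  }
  lam <- abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  vapply(seq_len(t_max), function(t) {
    lt <- lam^t
    s <- sum(lt)
    if (s <= 0) return(0)
    eta <- lt / s
    eta <- eta[eta > 0]
    -sum(eta * log(eta))
  }, numeric(1))
}

#' Select the diffusion time at the von Neumann entropy knee
#'
#' Scans `t = 1..t_max`, computing the von Neumann entropy of the diffused
#' operator from the (absolute) eigenvalues of its symmetric conjugate, and
#' returns the knee by the maximum-distance-to-chord rule. Falls back to
#' `t = 1` with a warning when the curve is flat.
#'
#' @param P row-stochastic diffusion operator.
#' @param t_max scan bound.
#' @param K optional kernel matrix `P` was derived from (gives the exact
#'   symmetric conjugate; otherwise `P` is symmetrised directly).
#' @return integer diffusion time.
#' @export
select_diffusion_time <- function(P, t_max = 100, K = NULL) {
  assert_matrix(P, "diffusion operator")
  if (any(abs(rowSums(P) - 1) > 1e-8)) {
    stop("P must be row-stochastic", call. = FALSE)
  }
  vne <- vne_curve(P, t_max = t_max, K = K)
  if (diff(range(vne)) < 1e-10) {
    warning("von Neumann entropy curve is flat; falling back to t = 1")
    return(1L)
  }
  as.integer(knee_point(seq_len(t_max), vne))
}

#' Potential distances of the diffused operator
#'
#' Euclidean distances between log-transformed rows of `P^t`, with
#' probabilities floored at `1e-12 * max(P^t)` before the logarithm.
#'
#' @param P row-stochastic operator.
#' @param t positive integer diffusion time.
#' @return symmetric `U x U` distance matrix with zero diagonal.
#' @export
potential_distances <- function(P, t) {
  assert_matrix(P, "diffusion operator")
  stopifnot(t >= 1, t == round(t))
  Pt <- mat_power(P, as.integer(t))
  floor_val <- 1e-12 * max(Pt)
  Pt[Pt < floor_val] <- floor_val
  row_dist(log(Pt))
}

# Matrix power by repeated squaring.
mat_power <- function(P, t) {
  if (t == 1L) return(P)
  out <- NULL
  base <- P
  while (t > 0) {
    if (t %% 2L == 1L) out <- if (is.null(out)) base else out %*% base
    t <- t %/% 2L
    if (t > 0) base <- base %*% base
  }
  out
}

#' Metric MDS by stress majorization
#'
#' SMACOF iterations initialised from classical MDS (deterministic); falls
#' back to a seeded random initialisation only if classical MDS is degenerate.
#'
#' @param D target distance matrix.
#' @param n_dims output dimensionality.
#' @param seed seed for the degenerate-initialisation fallback.
#' @param max_iter,tol iteration cap and relative stress-decrease tolerance.
#' @return list with `coords` (`U x n_dims`), `stress` (raw stress value) and
#'   `n_iter`; warns if the tolerance was not reached.
#' @export
mds_embed <- function(D, n_dims = 3, seed = 11L, max_iter = 100, tol = 1e-6) {
  assert_matrix(D, "distance matrix")
  n <- nrow(D)
  stopifnot(ncol(D) == n, n_dims >= 1, n_dims < n)
  X <- suppressWarnings(stats::cmdscale(D, k = n_dims))
  if (is.null(dim(X)) || ncol(X) < n_dims || anyNA(X)) {
    Xr <- with_rng(seed, matrix(stats::rnorm(n * n_dims), n, n_dims) * 1e-3)
    if (!is.null(dim(X)) && ncol(X) > 0) Xr[, seq_len(ncol(X))] <- X
    X <- Xr
  }
  stress <- function(d) sum((D - d)^2) / 2
  d <- row_dist(X)
  s_old <- stress(d)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    ratio <- ifelse(d > 0, D / d, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n
    d <- row_dist(X)
    s_new <- stress(d)
    if (s_old <= .Machine$double.eps || (s_old - s_new) / max(s_old, 1e-300) < tol) {
      s_old <- s_new
      converged <- TRUE
      break
    }
    s_old <- s_new
  }
  if (!converged) warning("MDS did not reach the stress tolerance in ", max_iter, " iterations")
  list(coords = X, stress = s_old, n_iter = iter)
}

#' Diffusion embedding of unique avalanche patterns
#'
#' Full composition: PCA, cosine distances, adaptive alpha-decay kernel,
#' Markov normalization, diffusion-time selection, potential distances, and
#' metric MDS. All intermediates are retained on the returned object.
#'
#' @param X `U x N` matrix of unique patterns (or any numeric feature matrix).
#' @param params an [embedding_params()] object.
#' @param keep_intermediates logical; retain kernel/operator/distances.
#' @return object of class `av_embedding` with `coords` (`U x n_dims`),
#'   `params`, `t`, `stress`, `explained_variance_ratio`, and (optionally)
#'   `kernel`, `operator`, `potential`.
#' @export
phate_embed <- function(X, params = embedding_params(), keep_intermediates = TRUE) {
  stopifnot(inherits(params, "embedding_params"))
  pca <- pca_reduce(X, params$n_pca)
  Dc <- cosine_distance_matrix(pca$scores)
  K <- alpha_decay_kernel(Dc, knn = params$knn, alpha = params$alpha)
  P <- markov_normalize(K)
  t_used <- if (identical(params$t, "auto")) {
    select_diffusion_time(P, t_max = params$t_max, K = K)
  } else as.integer(params$t)
  Dpot <- if (params$potential == "log") {
    potential_distances(P, t_used)
  } else {
    Pt <- mat_power(P, t_used)
    Dd <- Pt %*% Dc %*% t(Pt)
    Dd <- (Dd + t(Dd)) / 2
    diag(Dd) <- 0
    Dd
  }
  mds <- mds_embed(Dpot, n_dims = params$n_dims, seed = params$mds_seed,
                   max_iter = params$mds_max_iter)
  out <- list(coords = mds$coords, params = params, t = t_used,
              stress = mds$stress, mds_iter = mds$n_iter,
              explained_variance_ratio = pca$explained_variance_ratio,
              pca_scores = pca$scores)
  if (keep_intermediates) {
    out$cosine_distances <- Dc
    out$kernel <- K
    out$operator <- P
    out$potential <- Dpot
  }
  structure(out, class = "av_embedding")
}

#' @export
print.av_embedding <- function(x, ...) {
  cat(sprintf("<av_embedding> %d points in %d dims (t = %d, stress = %.4g)\n",
              nrow(x$coords), ncol(x$coords), x$t, x$stress))
  invisible(x)
}

#' PCA-only embedding (benchmark path)
#'
#' The comparison method: the first `n_dims` principal-component scores,
#' through the same interface as [phate_embed()].
#'
#' @inheritParams phate_embed
#' @return object of class `av_embedding` (coords are PCA scores; `t = 0`).
#' @export
pca_embed <- function(X, params = embedding_params()) {
  pca <- pca_reduce(X, max(params$n_pca, params$n_dims))
  structure(list(coords = pca$scores[, seq_len(params$n_dims), drop = FALSE],
                 params = params, t = 0L, stress = NA_real_,
                 explained_variance_ratio = pca$explained_variance_ratio,
                 pca_scores = pca$scores),
            class = "av_embedding")
}

#' kNN-distance diagnostic for the alpha-decay parameter
#'
#' Returns, for each point, the distance to each of its first `k_max`
#' nearest neighbours — the curve used to judge whether the kernel assigns
#' significant weight to the desired number of neighbours.
#'
#' @param D distance matrix.
#' @param k_max largest neighbour order reported.
#' @return `U x k_max` matrix; column j holds each point's j-th NN distance.
#' @export
knn_distance_curves <- function(D, k_max = 10) {
  assert_matrix(D, "distance matrix")
  n <- nrow(D)
  stopifnot(k_max <= n - 1)
  t(vapply(seq_len(n), function(i) sort(D[i, -i], method = "radix")[seq_len(k_max)],
           numeric(k_max)))
}
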