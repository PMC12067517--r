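# State identification: k-means over embedded patterns, with elbow,
# silhouette and gap-statistic model selection for the number of states.

#' K-means state clustering
#'
#' Seeded, best-of-`n_init` k-means (via [stats::kmeans()]) on embedding
#' coordinates. Deterministic given `seed`.
#'
#' @param coords `U x d` coordinate matrix.
#' @param k number of states (default 7).
#' @param seed integer seed.
#' @param n_init number of restarts.
#' @param max_iter iteration cap per restart.
#' @return object of class `state_model`: `labels` (1..k), `centroids`,
#'   `wcss` (total within-cluster sum of squares), `k`, `seed`, `n_init`.
#' @export
kmeans_states <- function(coords, k = 7, seed = 13L, n_init = 50,
                          max_iter = 300) {
  assert_matrix(coords, "coordinates")
  stopifnot(k >= 1, k <= nrow(coords))
  if (k == nrow(coords)) {
    # every point its own state
    return(structure(list(labels = seq_len(k), centroids = coords, wcss = 0,
                          k = as.integer(k), seed = as.integer(seed),
                          n_init = as.integer(n_init)),
                     class = "state_model"))
  }
  km <- with_rng(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      centers <- kmeanspp_centers(coords, k)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(coords, centers = centers,
                                       iter.max = max_iter)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
        best <- fit
      }
    }
    if (is.null(best)) stop("k-means failed for every restart", call. = FALSE)
    best
  })
  structure(list(labels = as.integer(km$cluster), centroids = km$centers,
                 wcss = km$tot.withinss, k = as.integer(k),
                 seed = as.integer(seed), n_init = as.integer(n_init)),
            class = "state_model")
}

# k-means++ seeding: first center uniform, subsequent centers drawn with
# probability proportional to squared distance from the nearest chosen center.
kmeanspp_centers <- function(coords, k) {
  n <- nrow(coords)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums((coords - rep(coords[idx[1], ], each = n))^2)
    for (j in 2:k) {
      if (all(d2 <= 0)) {
        idx[j] <- sample.int(n, 1)
      } else {
        idx[j] <- sample.int(n, 1, prob = d2)
      }
      d2 <- pmin(d2, rowSums((coords - rep(coords[idx[j], ], each = n))^2))
    }
  }
  coords[idx, , drop = FALSE] + stats::rnorm(k * ncol(coords), sd = 1e-10)
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> k = %d, %d points, wcss = %.4g\n",
              x$k, length(x$labels), x$wcss))
  invisible(x)
}

#' Elbow curve over candidate numbers of states
#'
#' WCSS per k (shared seed and restarts across k), with the knee reported by
#' the maximum-distance-to-chord rule.
#'
#' @inheritParams kmeans_states
#' @param k_range integer vector of candidate k.
#' @return list with `k_range`, `wcss`, `knee_k`.
#' @export
elbow_curve <- function(coords, k_range = 2:12, seed = 13L, n_init = 10) {
  wcss <- vapply(k_range, function(k) {
    kmeans_states(coords, k, seed = seed, n_init = n_init)$wcss
  }, numeric(1))
  knee_k <- if (length(k_range) >= 2) k_range[knee_point(k_range, wcss)] else k_range[1]
  list(k_range = as.integer(k_range), wcss = wcss, knee_k = as.integer(knee_k))
}

#' Silhouette of a clustering
#'
#' Mean and per-point silhouette widths ([cluster::silhouette()]); singleton
#' clusters receive width 0.
#'
#' @param coords coordinate matrix.
#' @param labels integer cluster labels (>= 2 distinct values).
#' @return list with `widths` (per point) and `mean`.
#' @export
silhouette_score <- function(coords, labels) {
  assert_matrix(coords, "coordinates")
  if (length(unique(labels)) < 2) {
    stop("silhouette requires at least 2 clusters", call. = FALSE)
  }
  sil <- cluster::silhouette(as.integer(labels), stats::dist(coords))
  widths <- sil[, "sil_width"]
  list(widths = as.numeric(widths), mean = mean(widths))
}

#' Gap statistic for the number of states
#'
#' `Gap(k) = mean_b log W_k(ref_b) - log W_k(data)` with `n_refs` reference
#' datasets drawn uniformly over the data's bounding box, and
#' `SE(k) = sd_b(log W_k) * sqrt(1 + 1/n_refs)`. Two recommendations are
#' reported: the k maximising the gap, and the Tibshirani one-SE rule
#' (smallest k with `Gap(k) >= Gap(k+1) - SE(k+1)`).
#'
#' @inheritParams elbow_curve
#' @param n_refs number of reference datasets.
#' @return list with `k_range`, `gap`, `se`, `log_wcss`, `recommended_k`
#'   (argmax), `tibshirani_k`.
#' @export
gap_statistic <- function(coords, k_range = 2:12, n_refs = 50, seed = 13L,
                          n_init = 10) {
  assert_matrix(coords, "coordinates")
  n <- nrow(coords); d <- ncol(coords)
  lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)
  logW <- function(X, k, s) log(kmeans_states(X, k, seed = s, n_init = n_init)$wcss)
  obs <- vapply(k_range, function(k) logW(coords, k, split_seed(seed, k)), numeric(1))
  ref_logW <- with_rng(seed, {
    vapply(seq_len(n_refs), function(b) {
      ref <- matrix(stats::runif(n * d, rep(lo, each = n), rep(hi, each = n)), n, d)
      vapply(k_range, function(k) logW(ref, k, split_seed(seed, 1000L + b * 100L + k)),
             numeric(1))
    }, numeric(length(k_range)))
  })
  ref_logW <- matrix(ref_logW, nrow = length(k_range))
  gap <- rowMeans(ref_logW) - obs
  se <- apply(ref_logW, 1, stats::sd) * sqrt(1 + 1 / n_refs)
  tib <- NA_integer_
  for (i in seq_along(k_range)) {
    if (i == length(k_range) || gap[i] >= gap[i + 1] - se[i + 1]) {
      tib <- k_range[i]
      break
    }
  }
  list(k_range = as.integer(k_range), gap = gap, se = se, log_wcss = obs,
       recommended_k = as.integer(k_range[which.max(gap)]),
       tibshirani_k = as.integer(tib))
}

#' Combined model-selection report
#'
#' Runs elbow, silhouette and gap statistic over one k range.
#'
#' @inheritParams gap_statistic
#' @return list with per-criterion curves and the recommended k of each.
#' @export
select_k_report <- function(coords, k_range = 2:12, n_refs = 50, seed = 13L,
                            n_init = 10) {
  elbow <- elbow_curve(coords, k_range, seed = seed, n_init = n_init)
  sil <- vapply(k_range[k_range >= 2], function(k) {
    silhouette_score(coords, kmeans_states(coords, k, seed = seed,
                                           n_init = n_init)$labels)$mean
  }, numeric(1))
  sil_k <- k_range[k_range >= 2][which.max(sil)]
  gap <- gap_statistic(coords, k_range, n_refs = n_refs, seed = seed,
                       n_init = n_init)
  list(k_range = as.integer(k_range), wcss = elbow$wcss,
       silhouette = sil, gap = gap$gap, gap_se = gap$se,
       recommended_k = list(elbow = elbow$knee_k,
                            silhouette = as.integer(sil_k),
                            gap = gap$recommended_k,
                            gap_tibshirani = gap$tibshirani_k))
}
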