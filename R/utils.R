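# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a stream-specific seed from a master seed
#'
#' Fixed splitting rule used throughout the package so that per-subject and
#' per-stage random streams are reproducible yet distinct: the master seed and
#' a stream index are combined linearly modulo the largest representable
#' integer.
#'
#' @param master integer master seed.
#' @param stream non-negative integer stream index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(master, stream) {
  m <- 2147483647 # 2^31 - 1
  as.integer((as.numeric(master) %% m * 48271 + as.numeric(stream) * 96797 + 1) %% (m - 1) + 1)
}

# Knee of a curve by maximum perpendicular distance to the chord joining the
# first and last points. Returns the index into `y` (and `x`).
knee_point <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  x0 <- x[1]; y0 <- y[1]
  x1 <- x[length(x)]; y1 <- y[length(y)]
  nx <- y1 - y0
  ny <- -(x1 - x0)
  nrm <- sqrt(nx^2 + ny^2)
  if (nrm < .Machine$double.eps) return(1L)
  d <- abs((x - x0) * nx + (y - y0) * ny) / nrm
  which.max(d)
}

# Pairwise Euclidean distances between rows of X, as a dense matrix.
# Uses the Gram-matrix identity so large inputs go through BLAS.
row_dist <- function(X) {
  X <- as.matrix(X)
  G <- tcrossprod(X)
  s <- diag(G)
  D2 <- outer(s, s, "+") - 2 * G
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  diag(D) <- 0
  D
}

# Validate that `x` is a numeric matrix without missing values.
assert_matrix <- function(x, what = "input") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  }
  if (anyNA(x)) stop(sprintf("%s contains missing values", what), call. = FALSE)
  invisible(x)
}
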