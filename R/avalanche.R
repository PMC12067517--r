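# Avalanche extraction: z-scoring, thresholding, interval detection and
# pattern vectorization. Conventions: sample indices are 0-based and
# intervals are half-open [start, end).

#' Construct a region-by-time signal container
#'
#' @param values `N x T` numeric matrix (regions in rows).
#' @param region_labels unique labels, one per region.
#' @param sampling_rate sampling rate in Hz.
#' @param subject_id subject label.
#' @return object of class `signal_set`.
#' @export
signal_set <- function(values, region_labels = NULL, sampling_rate = 256,
                       subject_id = "s01") {
  values <- as.matrix(values)
  assert_matrix(values, "signal values")
  if (nrow(values) < 1 || ncol(values) < 2) {
    stop("signal matrix must have >= 1 region and >= 2 samples", call. = FALSE)
  }
  if (is.null(region_labels)) region_labels <- sprintf("R%03d", seq_len(nrow(values)))
  if (length(region_labels) != nrow(values)) {
    stop("region_labels length must equal the number of rows", call. = FALSE)
  }
  if (anyDuplicated(region_labels)) {
    stop("duplicate region label: ",
         region_labels[duplicated(region_labels)][1], call. = FALSE)
  }
  rownames(values) <- region_labels
  structure(list(values = values, region_labels = as.character(region_labels),
                 sampling_rate = sampling_rate,
                 subject_id = as.character(subject_id)),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("<signal_set> subject %s: %d regions x %d samples @ %g Hz\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$sampling_rate))
  invisible(x)
}

#' Standardise each region's time series
#'
#' Subtracts the mean and divides by the population SD (divisor `T`), per
#' region over the full recording. Idempotent to numerical precision.
#'
#' @param signals a [signal_set()].
#' @return a [signal_set()] with zero-mean, unit-SD rows.
#' @export
zscore <- function(signals) {
  stopifnot(inherits(signals, "signal_set"))
  x <- signals$values
  mu <- rowMeans(x)
  xc <- x - mu
  sd_pop <- sqrt(rowMeans(xc^2))
  if (any(sd_pop <= 0)) {
    stop("constant signal in region ",
         signals$region_labels[which(sd_pop <= 0)[1]], call. = FALSE)
  }
  signals$values <- xc / sd_pop
  signals
}

#' Binarise z-scored signals at a fixed threshold
#'
#' A sample is active when its z-score exceeds the threshold strictly:
#' `|z| > threshold` in `absolute` mode (default) or `z > threshold` in
#' `positive` mode.
#'
#' @param z a z-scored [signal_set()].
#' @param threshold threshold in SD units (> 0); default 3.
#' @param mode `"absolute"` or `"positive"`.
#' @return object of class `binary_raster` with fields `active` (`N x T`
#'   0/1 integer matrix), `threshold`, `mode`, `subject_id`, `sampling_rate`.
#' @export
binarize <- function(z, threshold = 3, mode = c("absolute", "positive")) {
  stopifnot(inherits(z, "signal_set"), threshold > 0)
  mode <- match.arg(mode)
  v <- if (mode == "absolute") abs(z$values) else z$values
  active <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  active[v > threshold] <- 1L
  structure(list(active = active, threshold = threshold, mode = mode,
                 subject_id = z$subject_id, sampling_rate = z$sampling_rate,
                 region_labels = z$region_labels),
            class = "binary_raster")
}

#' Detect avalanche intervals
#'
#' An avalanche is a maximal run of consecutive samples during which at least
#' one region is active; it starts when any region crosses the threshold and
#' ends when no region is above it. Runs touching either end of the recording
#' are included.
#'
#' @param raster a [binarize()] output.
#' @return data.frame with columns `start` (0-based, inclusive), `end`
#'   (exclusive) and `subject_id`; zero rows when nothing is active.
#' @export
detect_avalanches <- function(raster) {
  stopifnot(inherits(raster, "binary_raster"))
  any_active <- colSums(raster$active) > 0
  r <- rle(any_active)
  ends_1b <- cumsum(r$lengths)
  starts_1b <- ends_1b - r$lengths + 1L
  keep <- r$values
  data.frame(start = as.integer(starts_1b[keep] - 1L),
             end = as.integer(ends_1b[keep]),
             subject_id = rep(raster$subject_id, sum(keep)),
             stringsAsFactors = FALSE)
}

#' Vectorise avalanches into binary patterns
#'
#' Each avalanche becomes a length-N binary vector with a 1 for every region
#' active at any sample of the interval (logical OR over time); the internal
#' spatiotemporal structure is discarded.
#'
#' @param raster a [binarize()] output.
#' @param intervals output of [detect_avalanches()] on the same raster.
#' @return object of class `pattern_sequence`: `patterns` (`n x N` matrix,
#'   chronological), `intervals`, `subject_ids`, `region_labels`.
#' @export
extract_patterns <- function(raster, intervals) {
  stopifnot(inherits(raster, "binary_raster"))
  n <- nrow(intervals)
  N <- nrow(raster$active)
  T_len <- ncol(raster$active)
  pat <- matrix(0L, n, N)
  colnames(pat) <- raster$region_labels
  for (i in seq_len(n)) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (s < 0 || e > T_len || s >= e) {
      stop("interval ", i, " [", s, ",", e, ") is out of range for the raster",
           call. = FALSE)
    }
    block <- raster$active[, (s + 1L):e, drop = FALSE]
    if (any(colSums(block) == 0)) {
      stop("interval ", i, " contains a silent column; not an avalanche interval",
           call. = FALSE)
    }
    pat[i, ] <- as.integer(rowSums(block) > 0)
  }
  structure(list(patterns = pat, intervals = intervals,
                 subject_ids = intervals$subject_id,
                 region_labels = raster$region_labels),
            class = "pattern_sequence")
}

#' @export
print.pattern_sequence <- function(x, ...) {
  cat(sprintf("<pattern_sequence> %d avalanches x %d regions (%d subject%s)\n",
              nrow(x$patterns), ncol(x$patterns),
              length(unique(x$subject_ids)),
              if (length(unique(x$subject_ids)) == 1) "" else "s"))
  invisible(x)
}

#' Full detection chain for one subject
#'
#' Composition `zscore` -> `binarize` -> `detect_avalanches` ->
#' `extract_patterns`.
#'
#' @inheritParams binarize
#' @param signals a raw [signal_set()].
#' @return a `pattern_sequence`.
#' @export
detect_subject <- function(signals, threshold = 3, mode = "absolute") {
  raster <- binarize(zscore(signals), threshold = threshold, mode = mode)
  extract_patterns(raster, detect_avalanches(raster))
}

#' Pool pattern sequences across subjects
#'
#' @param seqs list of `pattern_sequence` objects (one per subject).
#' @return a single `pattern_sequence`, subjects concatenated in order,
#'   chronological within subject.
#' @export
pool_patterns <- function(seqs) {
  stopifnot(length(seqs) >= 1, all(vapply(seqs, inherits, TRUE, "pattern_sequence")))
  structure(list(
    patterns = do.call(rbind, lapply(seqs, `[[`, "patterns")),
    intervals = do.call(rbind, lapply(seqs, `[[`, "intervals")),
    subject_ids = unlist(lapply(seqs, `[[`, "subject_ids"), use.names = FALSE),
    region_labels = seqs[[1]]$region_labels
  ), class = "pattern_sequence")
}

#' Deduplicate avalanche patterns
#'
#' Unique patterns (exact binary equality, first-occurrence order) are the
#' input to the embedding; the occurrence index maps every avalanche back to
#' its unique row so state labels can be propagated.
#'
#' @param seq a `pattern_sequence`.
#' @param scope `"pooled"` (dedupe across subjects, default) or
#'   `"per_subject"`.
#' @return list with `patterns` (`U x N` matrix) and `index` (length-n map
#'   into rows of `patterns`); for `per_subject` scope, a list of such pairs.
#' @export
unique_patterns <- function(seq, scope = c("pooled", "per_subject")) {
  scope <- match.arg(scope)
  stopifnot(inherits(seq, "pattern_sequence"), nrow(seq$patterns) >= 1)
  dedupe <- function(m) {
    key <- apply(m, 1, paste, collapse = "")
    first <- !duplicated(key)
    list(patterns = m[first, , drop = FALSE],
         index = match(key, key[first]))
  }
  if (scope == "pooled") return(dedupe(seq$patterns))
  ids <- unique(seq$subject_ids)
  out <- lapply(ids, function(id) dedupe(seq$patterns[seq$subject_ids == id, , drop = FALSE]))
  names(out) <- ids
  out
}

#' Summary statistics of detected avalanches
#'
#' @param raster a [binarize()] output.
#' @param intervals output of [detect_avalanches()] on the same raster.
#' @return list with `count`, `sizes` (regions recruited per avalanche),
#'   `durations` (samples), and `time_fraction` (fraction of samples inside
#'   an avalanche).
#' @export
avalanche_summary <- function(raster, intervals) {
  stopifnot(inherits(raster, "binary_raster"))
  durations <- intervals$end - intervals$start
  sizes <- if (nrow(intervals) > 0) {
    ps <- extract_patterns(raster, intervals)
    rowSums(ps$patterns)
  } else numeric(0)
  list(count = nrow(intervals), sizes = as.numeric(sizes),
       durations = as.numeric(durations),
       time_fraction = sum(durations) / ncol(raster$active))
}
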