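test_that("z-scoring standardises, is idempotent, and rejects constants", {
  s <- signal_set(rbind(c(1, 2, 3), c(4, 0, 2)), sampling_rate = 1)
  z <- zscore(s)
  expect_equal(z$values[1, ], c(-1.224745, 0, 1.224745),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(rowMeans(z$values), c(0, 0), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(rowMeans(z$values^2), c(1, 1), tolerance = 1e-10,
               ignore_attr = TRUE) # population SD
  z2 <- zscore(z)
  expect_equal(z2$values, z$values, tolerance = 1e-10)

  expect_error(zscore(signal_set(rbind(c(5, 5, 5), c(1, 2, 3)),
                                 region_labels = c("bad", "ok"))),
               "bad")
})

test_that("binarization uses a strict threshold in both modes", {
  z <- signal_set(matrix(c(0, 3.1, -3.5, 2.9, 3.0, -3.0), 1),
                  sampling_rate = 1)
  expect_equal(unname(binarize(z, 3)$active[1, ]), c(0, 1, 1, 0, 0, 0))
  expect_equal(unname(binarize(z, 3, mode = "positive")$active[1, ]),
               c(0, 1, 0, 0, 0, 0))
})

test_that("supra-threshold rate on Gaussian noise matches the normal tail", {
  T_len <- 1e6
  s <- signal_set(matrix(withr::with_seed(123, stats::rnorm(T_len)), 1),
                  sampling_rate = 256)
  r <- binarize(zscore(s), 3, mode = "positive")
  p_tail <- stats::pnorm(3, lower.tail = FALSE) # 0.00135
  frac <- mean(r$active)
  se <- sqrt(p_tail * (1 - p_tail) / T_len)
  expect_lt(abs(frac - p_tail), 3 * se)
})

test_that("avalanche detection matches a brute-force column scan", {
  mk <- function(cols) {
    structure(list(active = rbind(cols, 0L), threshold = 3,
                   mode = "absolute", subject_id = "s", sampling_rate = 1,
                   region_labels = c("a", "b")),
              class = "binary_raster")
  }
  iv <- detect_avalanches(mk(c(0L, 1L, 1L, 0L, 1L, 0L)))
  expect_equal(iv$start, c(1L, 4L))
  expect_equal(iv$end, c(3L, 5L))
  expect_equal(nrow(detect_avalanches(mk(rep(0L, 6)))), 0)

  # random rasters vs exhaustive per-column scan oracle
  for (seed in 1:5) {
    active <- withr::with_seed(seed,
      matrix(rbinom(5 * 200, 1, 0.08), 5, 200))
    raster <- structure(list(active = active, threshold = 3,
                             mode = "absolute", subject_id = "s",
                             sampling_rate = 1,
                             region_labels = paste0("r", 1:5)),
                        class = "binary_raster")
    iv <- detect_avalanches(raster)
    # oracle: walk columns one by one
    on_cols <- colSums(active) > 0
    runs <- list(); cur <- NULL
    for (t in seq_along(on_cols)) {
      if (on_cols[t] && is.null(cur)) cur <- t
      if (!on_cols[t] && !is.null(cur)) { runs[[length(runs) + 1]] <- c(cur, t); cur <- NULL }
    }
    if (!is.null(cur)) runs[[length(runs) + 1]] <- c(cur, length(on_cols) + 1)
    expect_equal(iv$start, vapply(runs, `[`, 0, 1) - 1L)
    expect_equal(iv$end, vapply(runs, `[`, 0, 2) - 1L)
    # conservation: interval columns are exactly the active columns
    covered <- unlist(mapply(function(s, e) (s + 1):e, iv$start, iv$end,
                             SIMPLIFY = FALSE))
    expect_equal(sort(covered), which(on_cols))
  }
})

test_that("patterns are the OR over the interval", {
  active <- matrix(0L, 3, 6)
  active[1, 2] <- 1L; active[3, 3] <- 1L; active[2, 5] <- 1L
  raster <- structure(list(active = active, threshold = 3, mode = "absolute",
                           subject_id = "s", sampling_rate = 1,
                           region_labels = paste0("r", 1:3)),
                      class = "binary_raster")
  iv <- detect_avalanches(raster)
  ps <- extract_patterns(raster, iv)
  expect_equal(unname(ps$patterns[1, ]), c(1L, 0L, 1L)) # OR of t=1..2
  expect_equal(unname(ps$patterns[2, ]), c(0L, 1L, 0L)) # single column
  expect_error(extract_patterns(raster, data.frame(start = 0, end = 2,
                                                   subject_id = "s")),
               "silent")
})

test_that("detection chain is invariant to per-region affine rescaling", {
  co <- small_cohort()
  s <- co$signals[[1]]
  s2 <- s
  scale <- withr::with_seed(1, stats::runif(nrow(s$values), 0.5, 4))
  shift <- withr::with_seed(2, stats::rnorm(nrow(s$values), sd = 10))
  s2$values <- s$values * scale + shift
  a <- detect_subject(s)
  b <- detect_subject(s2)
  expect_equal(a$intervals, b$intervals)
  expect_equal(a$patterns, b$patterns)
})

test_that("unique patterns match a sort-based oracle and map occurrences", {
  pat <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1))
  seq0 <- structure(list(patterns = pat,
                         intervals = data.frame(start = 0:2, end = 1:3,
                                                subject_id = rep("s", 3)),
                         subject_ids = rep("s", 3),
                         region_labels = paste0("r", 1:4)),
                    class = "pattern_sequence")
  uq <- unique_patterns(seq0)
  expect_equal(nrow(uq$patterns), 2)
  expect_equal(uq$index, c(1, 1, 2))

  pat2 <- random_patterns(1000, 10, 3, seed = 42)
  seq2 <- structure(list(patterns = pat2,
                         intervals = data.frame(start = seq_len(1000) - 1,
                                                end = seq_len(1000),
                                                subject_id = rep("s", 1000)),
                         subject_ids = rep("s", 1000),
                         region_labels = paste0("r", 1:10)),
                    class = "pattern_sequence")
  uq2 <- unique_patterns(seq2)
  n_oracle <- nrow(unique(as.data.frame(pat2)))
  expect_equal(nrow(uq2$patterns), n_oracle)
  expect_equal(uq2$patterns[uq2$index, ], pat2, ignore_attr = TRUE)
})

test_that("avalanche summary reports counts, durations and sparsity", {
  active <- rbind(c(0L, 1L, 1L, 0L, 1L, 0L))
  raster <- structure(list(active = active, threshold = 3, mode = "absolute",
                           subject_id = "s", sampling_rate = 1,
                           region_labels = "r1"),
                      class = "binary_raster")
  sm <- avalanche_summary(raster, detect_avalanches(raster))
  expect_equal(sm$count, 2)
  expect_equal(sort(sm$durations), c(1, 2))
  expect_equal(sm$time_fraction, 0.5)

  empty <- raster; empty$active[] <- 0L
  sm0 <- avalanche_summary(empty, detect_avalanches(empty))
  expect_equal(sm0$count, 0)
  expect_equal(sm0$time_fraction, 0)

  # default synthetic regime is sparse, mirroring resting-state avalanches
  co <- small_cohort()
  r <- binarize(zscore(co$signals[[1]]))
  smc <- avalanche_summary(r, detect_avalanches(r))
  expect_lt(smc$time_fraction, 0.05)
})
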