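test_that("topographies count region recruitment per state", {
  pat <- rbind(c(1, 1, 0, 0), c(1, 0, 1, 0), c(0, 0, 0, 1))
  topo <- cluster_topographies(pat, c(1L, 1L, 2L))
  expect_equal(unname(topo$fractions[1, ]), c(1, 0.5, 0.5, 0))
  expect_equal(unname(topo$fractions[2, ]), c(0, 0, 0, 1)) # single pattern
  expect_equal(topo$cluster_sizes, c(2L, 1L))
  expect_equal(topo$counts / topo$cluster_sizes, topo$fractions,
               ignore_attr = TRUE)
  expect_error(cluster_topographies(pat, c(1L, 1L, 1L), n_states = 2),
               "empty cluster")
})

test_that("planted topographies are recovered from a fixture cohort", {
  co <- small_cohort()
  pooled <- cohort_patterns(co)
  planted <- unlist(co$truth$state_sequence)
  topo <- cluster_topographies(pooled$patterns, planted, 4)
  mc <- match_clusterings(topo$fractions, co$truth$topographies)
  expect_true(all(mc$row_max >= 0.95))
})

test_that("label propagation preserves order and length", {
  expect_equal(propagate_labels(c(7L, 9L), c(1, 1, 2)), c(7L, 7L, 9L))
  expect_equal(propagate_labels(5L, 1L), 5L)
  expect_error(propagate_labels(c(1L, 2L), c(1, 3)), "out of range")

  co <- small_cohort()
  pooled <- cohort_patterns(co)
  uq <- unique_patterns(pooled)
  lab <- propagate_labels(seq_len(nrow(uq$patterns)), uq$index)
  seqs <- split_sequences(lab, pooled$subject_ids)
  expect_equal(lengths(seqs),
               vapply(split(pooled$subject_ids, pooled$subject_ids), length, 1L)[names(seqs)])
})

test_that("transition matrices count consecutive pairs and normalise rows", {
  tm <- transition_matrix(c(1L, 1L, 2L, 2L, 1L), 2)
  expect_equal(unname(tm$counts), rbind(c(1L, 1L), c(1L, 1L)))
  expect_equal(unname(tm$probs), matrix(0.5, 2, 2))

  tm3 <- transition_matrix(c(3L, 3L, 3L), 3)
  expect_equal(unname(tm3$probs[3, ]), c(0, 0, 1))
  expect_equal(tm3$zero_rows, c(TRUE, TRUE, FALSE), ignore_attr = TRUE)

  # long simulated chain within 3 binomial SE per cell
  P <- make_planted_transition(3, 0.25)
  chain <- withr::with_seed(21, {
    s <- integer(20000); s[1] <- 1L
    for (i in 2:20000) s[i] <- sample.int(3, 1, prob = P[s[i - 1], ])
    s
  })
  tmc <- transition_matrix(chain, 3)
  se <- sqrt(P * (1 - P) / rowSums(tmc$counts))
  expect_true(all(abs(tmc$probs - P) <= 3 * se))
})

test_that("pooling respects the boundary policy", {
  seqs <- list(s1 = c(1L, 2L), s2 = c(2L, 1L))
  excl <- pooled_transition_matrix(seqs, 2, boundary_policy = "exclude")
  expect_equal(unname(excl$counts), rbind(c(0L, 1L), c(1L, 0L)))
  incl <- pooled_transition_matrix(seqs, 2, boundary_policy = "include")
  expect_equal(unname(incl$counts), rbind(c(0L, 1L), c(1L, 1L)))

  # include vs exclude differ by exactly n_subjects - 1 counts
  co <- small_cohort()
  pooled <- cohort_patterns(co)
  seqs4 <- split_sequences(unlist(co$truth$state_sequence),
                           pooled$subject_ids)
  d <- sum(pooled_transition_matrix(seqs4, 4, "include")$counts) -
    sum(pooled_transition_matrix(seqs4, 4, "exclude")$counts)
  expect_equal(d, length(seqs4) - 1)

  # conservation: total counts = sum of (length - 1)
  expect_equal(sum(pooled_transition_matrix(seqs4, 4, "exclude")$counts),
               sum(lengths(seqs4) - 1))
  # row-stochasticity preserved under pooling
  ctm <- pooled_transition_matrix(seqs4, 4)
  expect_equal(rowSums(ctm$probs[!ctm$zero_rows, ]),
               rep(1, sum(!ctm$zero_rows)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("transition variability shrinks with sequence length", {
  tmA <- transition_matrix(c(1L, 2L, 1L, 2L, 1L), 2, "a")
  tv0 <- transition_variability(list(tmA, tmA))
  expect_equal(max(tv0$sd), 0)
  expect_equal(max(tv0$cv, na.rm = TRUE), 0)

  # two subjects, hand-computed population SD
  tmB <- transition_matrix(c(1L, 1L, 1L, 2L, 1L, 2L), 2, "b")
  tv <- transition_variability(list(tmA, tmB))
  cellA <- tmA$probs[1, 1]; cellB <- tmB$probs[1, 1]
  expect_equal(tv$mean[1, 1], mean(c(cellA, cellB)))
  expect_equal(tv$sd[1, 1], abs(cellA - cellB) / 2)

  # CV decreases as per-subject sequences grow
  P <- make_planted_transition(3, 0.2)
  cv_at_len <- function(len) {
    tms <- lapply(1:8, function(s) {
      chain <- withr::with_seed(100 + s, {
        x <- integer(len); x[1] <- 1L
        for (i in 2:len) x[i] <- sample.int(3, 1, prob = P[x[i - 1], ])
        x
      })
      transition_matrix(chain, 3)
    })
    mean(transition_variability(tms)$cv, na.rm = TRUE)
  }
  cvs <- vapply(c(50, 400, 3200), cv_at_len, numeric(1))
  expect_true(all(diff(cvs) < 0))
})

test_that("clustering matching is permutation-invariant and handles constants", {
  topo <- withr::with_seed(31, matrix(stats::runif(5 * 20), 5, 20))
  self <- match_clusterings(topo, topo)
  expect_equal(self$avg_max_correlation, 1, tolerance = 1e-12)
  shuf <- match_clusterings(topo, topo[c(3, 1, 5, 2, 4), ])
  expect_equal(shuf$avg_max_correlation, 1, tolerance = 1e-12)
  expect_equal(shuf$matching$b[shuf$matching$a], c(2, 4, 1, 5, 3))

  topo_const <- rbind(rep(0.5, 20), topo[1, ])
  expect_warning(mc <- match_clusterings(topo_const, topo), "constant")
  expect_true(all(is.finite(mc$correlation)))
})

test_that("threshold scan is stable when bursts dominate all thresholds", {
  co <- small_cohort()
  # bursts sit near 5 SD after z-scoring while truncated background stays
  # below 3: every threshold in between selects the same avalanches
  scan <- suppressWarnings(threshold_sensitivity_scan(
    co$signals, thresholds = c(3, 3.2, 3.5), k = 4,
    params = embedding_params(), seed = 13))
  expect_equal(length(unique(scan$n_avalanches)), 1)
  expect_equal(scan$correlation_with_reference, rep(1, 3), tolerance = 1e-6)
  # a threshold nothing exceeds is recorded as missing, not fatal
  scan_hi <- suppressWarnings(threshold_sensitivity_scan(
    co$signals, thresholds = 50, k = 4, seed = 13))
  expect_true(is.na(scan_hi$entropy))
  expect_equal(scan_hi$n_avalanches, 0L)
})
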