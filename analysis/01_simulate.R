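#!/usr/bin/env Rscript
# Simulate the synthetic study cohort: 18 subjects, 90 regions at 256 Hz for
# 6 minutes each, 7 planted states (12 regions each, pairwise Jaccard
# overlap <= 0.2), ~200 transient events per subject drawn from a Markov
# chain with a 0.1 self-transition bias, bursts at 6 SD on a truncated
# Gaussian background. Writes the ground truth and one example subject;
# later scripts re-simulate deterministically from the same seed instead of
# re-reading the (large) signal matrices.

library(avstates)

SEED <- 20260922L
dir.create("results", showWarnings = FALSE)

params <- sim_params(seed = SEED)
cohort <- simulate_cohort(params)

# first 8 s of subject 1 as an inspectable excerpt (the full matrices are
# ~80 MB of text each; re-simulate from the seed instead of storing them)
excerpt <- cohort$signals[[1]]
excerpt$values <- round(excerpt$values[, 1:2048], 5)
write_signals(excerpt, "results/signals_s01_excerpt.tsv")
utils::write.table(cohort$truth$topographies, "results/planted_topographies.tsv",
                   sep = "\t", quote = FALSE)
utils::write.table(cohort$truth$planted_transition,
                   "results/planted_transition.tsv", sep = "\t", quote = FALSE)
utils::write.table(cohort$truth$intervals, "results/planted_intervals.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
jsonlite::write_json(
  list(seed = SEED, params = unclass(params),
       n_events = lengths(cohort$truth$state_sequence)),
  "results/simulation_manifest.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

cat(sprintf("simulated %d subjects, %d planted avalanches in total\n",
            params$n_subjects, nrow(cohort$truth$intervals)))
cat(sprintf("first subject: %d events over %d samples (%.1f%% of time)\n",
            length(cohort$truth$state_sequence[[1]]),
            ncol(cohort$signals[[1]]$values),
            100 * sum(cohort$truth$intervals$end[cohort$truth$intervals$subject_id == "s01"] -
                      cohort$truth$intervals$start[cohort$truth$intervals$subject_id == "s01"]) /
              ncol(cohort$signals[[1]]$values)))
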