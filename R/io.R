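# Readers, writers, pipeline configuration and the end-to-end driver.
# TSV is the interchange format throughout; JSON for structured summaries.

#' Write a signal set as TSV
#'
#' Layout: a `#` metadata line (`sampling_rate`, `subject_id`), a header row
#' of 0-based sample indices, then one row per region with the region label
#' in the first column.
#'
#' @param signals a [signal_set()].
#' @param path output file.
#' @export
write_signals <- function(signals, path) {
  stopifnot(inherits(signals, "signal_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate=%s subject_id=%s",
                     format(signals$sampling_rate), signals$subject_id), con)
  writeLines(paste(c("region", seq_len(ncol(signals$values)) - 1L),
                   collapse = "\t"), con)
  utils::write.table(
    data.frame(region = signals$region_labels, signals$values,
               check.names = FALSE),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
}

#' Read a signal set from TSV
#'
#' Inverse of [write_signals()]; validates the header, numeric cells and
#' region-label uniqueness with line-numbered messages.
#'
#' @param path input file.
#' @return a [signal_set()].
#' @export
read_signals <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("file too short to be a signal TSV: ", path, call. = FALSE)
  meta <- lines[1]
  if (!startsWith(meta, "#")) {
    stop(path, ":1: expected a '# sampling_rate=... subject_id=...' metadata line",
         call. = FALSE)
  }
  sr <- sub(".*sampling_rate=([0-9.eE+-]+).*", "\\1", meta)
  sid <- sub(".*subject_id=([^ ]+).*", "\\1", meta)
  header <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (header[1] != "region") {
    stop(path, ":2: header must start with 'region'", call. = FALSE)
  }
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  labels <- vapply(body, `[[`, "", 1)
  if (anyDuplicated(labels)) {
    stop(path, ": duplicate region label '", labels[duplicated(labels)][1], "'",
         call. = FALSE)
  }
  vals <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (anyNA(v)) {
      stop(path, ":", i + 2L, ": non-numeric cell in region '", labels[i], "'",
           call. = FALSE)
    }
    v
  })
  signal_set(do.call(rbind, vals), region_labels = labels,
             sampling_rate = as.numeric(sr), subject_id = sid)
}

#' Write avalanche patterns as TSV
#'
#' One row per avalanche: `subject_id`, `start`, `end`, then one 0/1 column
#' per region.
#'
#' @param seq a `pattern_sequence`.
#' @param path output file.
#' @export
write_patterns <- function(seq, path) {
  stopifnot(inherits(seq, "pattern_sequence"))
  df <- data.frame(subject_id = seq$subject_ids,
                   start = seq$intervals$start, end = seq$intervals$end,
                   seq$patterns, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read avalanche patterns from TSV
#'
#' @param path file written by [write_patterns()].
#' @return a `pattern_sequence`.
#' @export
read_patterns <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  pat <- as.matrix(df[, -(1:3), drop = FALSE])
  storage.mode(pat) <- "integer"
  structure(list(patterns = pat,
                 intervals = data.frame(start = df$start, end = df$end,
                                        subject_id = df$subject_id,
                                        stringsAsFactors = FALSE),
                 subject_ids = df$subject_id,
                 region_labels = colnames(pat)),
            class = "pattern_sequence")
}

#' Write avalanche intervals as BED-like TSV
#'
#' Three columns — subject, start, end — half-open, 0-based.
#'
#' @param intervals data.frame from [detect_avalanches()].
#' @param path output file.
#' @export
write_intervals <- function(intervals, path) {
  utils::write.table(intervals[, c("subject_id", "start", "end")], path,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

#' Pipeline configuration
#'
#' Defaults are the standard analysis settings: threshold 3 SD (absolute
#' mode), 5 principal components, 5 nearest neighbours, alpha-decay 1,
#' 3 embedding dimensions, k = 7 states, 10000 permutations per null,
#' exclude-boundary pooling.
#'
#' @param threshold binarization threshold (SD units).
#' @param mode binarization mode.
#' @param embedding an [embedding_params()] object.
#' @param k number of states.
#' @param n_init k-means restarts.
#' @param boundary_policy pooled-transition boundary policy.
#' @param n_perm permutations for nulls 1-2 (null 3 defaults to 99).
#' @param n_perm_region permutations for null 3.
#' @param nulls character subset of `c("labels", "sequence", "regions")`.
#' @param seed master seed (stage seeds derived with [split_seed()]).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold = 3, mode = "absolute",
                            embedding = embedding_params(), k = 7,
                            n_init = 50, boundary_policy = "exclude",
                            n_perm = 10000, n_perm_region = 99,
                            nulls = character(), seed = 17L) {
  stopifnot(threshold > 0, inherits(embedding, "embedding_params"), k >= 1,
            all(nulls %in% c("labels", "sequence", "regions")))
  structure(list(threshold = threshold, mode = mode, embedding = embedding,
                 k = as.integer(k), n_init = as.integer(n_init),
                 boundary_policy = boundary_policy,
                 n_perm = as.integer(n_perm),
                 n_perm_region = as.integer(n_perm_region),
                 nulls = nulls, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end pipeline
#'
#' Detection -> pooled unique patterns -> diffusion embedding -> k-means ->
#' label propagation -> topographies -> per-subject and pooled transition
#' matrices -> requested null models. All effective parameters are echoed in
#' the returned manifest.
#'
#' @param signals list of [signal_set()] objects (one per subject).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, all artifacts are written
#'   (TSV/JSON) together with a run manifest.
#' @return list with `patterns`, `unique`, `embedding`, `states`, `labels`
#'   (per avalanche), `sequences` (per subject), `topographies`,
#'   `transition_subject`, `transition_pooled`, `variability`, `nulls`,
#'   `manifest`.
#' @export
run_pipeline <- function(signals, config = pipeline_config(), out_dir = NULL) {
  stopifnot(length(signals) >= 1, inherits(config, "pipeline_config"))
  seqs <- lapply(signals, detect_subject, threshold = config$threshold,
                 mode = config$mode)
  pooled <- pool_patterns(seqs)
  if (nrow(pooled$patterns) == 0) stop("no avalanches detected", call. = FALSE)
  uq <- unique_patterns(pooled)
  emb <- phate_embed(uq$patterns, config$embedding)
  states <- kmeans_states(emb$coords, k = config$k,
                          seed = split_seed(config$seed, 1L),
                          n_init = config$n_init)
  labels <- propagate_labels(states$labels, uq$index)
  sequences <- split_sequences(labels, pooled$subject_ids)
  topo <- cluster_topographies(pooled$patterns, labels, n_states = config$k)
  tms <- lapply(names(sequences), function(id) {
    transition_matrix(sequences[[id]], n_states = config$k, subject_id = id)
  })
  names(tms) <- names(sequences)
  ctm <- pooled_transition_matrix(sequences, n_states = config$k,
                                  boundary_policy = config$boundary_policy)
  nulls <- list()
  if ("labels" %in% config$nulls) {
    nulls$labels <- null_label_shuffle(pooled$patterns, labels,
                                       n_perm = config$n_perm,
                                       seed = split_seed(config$seed, 2L),
                                       n_states = config$k)
  }
  if ("sequence" %in% config$nulls) {
    nulls$sequence <- null_sequence_shuffle(sequences, n_states = config$k,
                                            n_perm = config$n_perm,
                                            seed = split_seed(config$seed, 3L),
                                            boundary_policy = config$boundary_policy)
  }
  if ("regions" %in% config$nulls) {
    nulls$regions <- null_region_shuffle(pooled$patterns, k = config$k,
                                         params = config$embedding,
                                         n_perm = config$n_perm_region,
                                         seed = split_seed(config$seed, 4L),
                                         cluster_seed = split_seed(config$seed, 1L))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("avstates")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass_config(config),
    n_subjects = length(signals),
    n_avalanches = nrow(pooled$patterns),
    n_unique = nrow(uq$patterns),
    diffusion_time = emb$t
  )
  out <- list(patterns = pooled, unique = uq, embedding = emb,
              states = states, labels = labels, sequences = sequences,
              topographies = topo, transition_subject = tms,
              transition_pooled = ctm,
              variability = transition_variability(tms),
              nulls = nulls, manifest = manifest)
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

unclass_config <- function(config) {
  cfg <- unclass(config)
  cfg$embedding <- unclass(cfg$embedding)
  cfg
}

# Write the artifact bundle of a run to a directory.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_patterns(run$patterns, file.path(out_dir, "patterns.tsv"))
  write_intervals(run$patterns$intervals, file.path(out_dir, "intervals.tsv"))
  emb_df <- data.frame(pattern = seq_len(nrow(run$embedding$coords)),
                       occurrences = tabulate(run$unique$index,
                                              nrow(run$embedding$coords)),
                       run$embedding$coords)
  names(emb_df)[-(1:2)] <- paste0("dim", seq_len(ncol(run$embedding$coords)))
  utils::write.table(emb_df, file.path(out_dir, "embedding.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(pattern = seq_along(run$labels), label = run$labels),
    file.path(out_dir, "labels.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(run$topographies$fractions,
                     file.path(out_dir, "topographies.tsv"), sep = "\t",
                     quote = FALSE)
  utils::write.table(run$transition_pooled$probs,
                     file.path(out_dir, "transition_pooled.tsv"), sep = "\t",
                     quote = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(run$nulls) > 0) {
    nn <- lapply(run$nulls, function(nl) {
      keep <- nl[intersect(names(nl), c("observed", "p_low", "p_high",
                                        "n_perm", "seed", "alpha"))]
      if (inherits(keep$observed, "transition_matrix")) {
        keep$observed <- keep$observed$probs
      }
      if (is.matrix(keep$p_low)) {
        keep$n_significant <- sum(nl$mask != 0)
        keep$p_low <- NULL
        keep$p_high <- NULL
      }
      keep
    })
    jsonlite::write_json(nn, file.path(out_dir, "nulls.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}

#' Human-readable run report
#'
#' @param run output of [run_pipeline()].
#' @return character vector of report lines (also printed).
#' @export
report <- function(run) {
  lines <- c(
    sprintf("subjects: %d", run$manifest$n_subjects),
    sprintf("avalanches: %d (unique patterns: %d)",
            run$manifest$n_avalanches, run$manifest$n_unique),
    sprintf("diffusion time t = %d, MDS stress = %.4g",
            run$embedding$t, run$embedding$stress),
    sprintf("states: k = %d, wcss = %.4g", run$states$k, run$states$wcss),
    sprintf("topography entropy H = %.4f nats",
            cluster_entropy(run$topographies$fractions)$H),
    sprintf("pooled CTM diagonal mean = %.4f",
            mean(diag(run$transition_pooled$probs)))
  )
  if (length(run$nulls) == 0) {
    lines <- c(lines, "null models: not computed")
  } else {
    for (nm in names(run$nulls)) {
      nl <- run$nulls[[nm]]
      lines <- c(lines, if (nm == "sequence") {
        sprintf("null (sequence): %d/%d cells significant at %.2f",
                sum(nl$mask != 0), length(nl$mask), nl$alpha)
      } else {
        sprintf("null (%s): H = %.4f, p_low = %.4g, p_high = %.4g",
                nm, nl$observed, nl$p_low, nl$p_high)
      })
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
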