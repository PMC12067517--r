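# Synthetic cohort generator: multichannel signals with planted avalanche
# states and a known state-transition Markov chain, giving every downstream
# stage a ground truth to validate against.

#' AAL-90 region labels
#'
#' Labels for the 90-region anatomical parcellation (45 homologous pairs,
#' left/right) conventionally used as the spatial dimension of avalanche
#' patterns.
#'
#' @return character vector of length 90.
#' @export
aal90_labels <- function() {
  base <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf"
  )
  as.vector(rbind(paste0(base, "_L"), paste0(base, "_R")))
}

#' Simulation parameters for the synthetic cohort
#'
#' Defaults emulate the regime the pipeline is designed for: 90 regions
#' sampled at 256 Hz for 6 minutes per subject, 18 subjects, and sparse
#' transient events (about 200 per subject, mean 20 samples each, so roughly
#' 4% of time points fall inside an avalanche) drawn from a planted Markov
#' chain over 7 states.
#'
#' Background noise is standard Gaussian per region per sample (optionally
#' AR(1)); in fixture mode (the default) it is truncated at |z| = 2.9 so that
#' only planted events cross the downstream 3-SD threshold and ground truth
#' is exact. Untruncated noise (`fixture_mode = FALSE`) is available for
#' stress-testing the detector against chance crossings.
#'
#' @param n_regions number of regions (rows of the signal matrix).
#' @param n_states number of planted states.
#' @param sampling_rate sampling rate in Hz.
#' @param duration recording length per subject, seconds.
#' @param n_subjects cohort size.
#' @param event_rate expected avalanches per second.
#' @param event_duration_mean mean event duration, samples (geometric, min 1).
#' @param burst_amplitude additive burst height in units of the background SD;
#'   must exceed the downstream binarization threshold.
#' @param membership_recruitment_prob probability that a member region of the
#'   active state is recruited in a given event.
#' @param regions_per_state regions per planted topography.
#' @param topography_overlap maximum pairwise Jaccard overlap between states.
#' @param noise_model `"white"` or `"ar1"`.
#' @param ar_coef AR(1) coefficient when `noise_model = "ar1"`.
#' @param self_transition_bias extra probability mass on the diagonal of the
#'   planted transition matrix (see [make_planted_transition()]).
#' @param fixture_mode logical; truncate background noise at |z| = 2.9.
#' @param seed master seed; per-subject streams are derived with
#'   [split_seed()].
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_regions = 90, n_states = 7, sampling_rate = 256,
                       duration = 360, n_subjects = 18, event_rate = 0.55,
                       event_duration_mean = 20, burst_amplitude = 6,
                       membership_recruitment_prob = 0.8,
                       regions_per_state = 12, topography_overlap = 0.2,
                       noise_model = c("white", "ar1"), ar_coef = 0.5,
                       self_transition_bias = 0.1, fixture_mode = TRUE,
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  p <- list(
    n_regions = as.integer(n_regions), n_states = as.integer(n_states),
    sampling_rate = sampling_rate, duration = duration,
    n_subjects = as.integer(n_subjects), event_rate = event_rate,
    event_duration_mean = event_duration_mean,
    burst_amplitude = burst_amplitude,
    membership_recruitment_prob = membership_recruitment_prob,
    regions_per_state = as.integer(regions_per_state),
    topography_overlap = topography_overlap, noise_model = noise_model,
    ar_coef = ar_coef, self_transition_bias = self_transition_bias,
    fixture_mode = isTRUE(fixture_mode), seed = as.integer(seed)
  )
  stopifnot(
    p$n_regions >= 1, p$n_states >= 1, p$sampling_rate > 0, p$duration > 0,
    p$n_subjects >= 1, p$event_rate >= 0, p$event_duration_mean >= 1,
    p$burst_amplitude > 0,
    p$membership_recruitment_prob > 0, p$membership_recruitment_prob <= 1,
    p$regions_per_state >= 1, p$regions_per_state <= p$n_regions,
    p$topography_overlap >= 0, p$topography_overlap < 1,
    p$self_transition_bias >= 0, p$self_transition_bias <= 1
  )
  if (p$event_rate * p$event_duration_mean / p$sampling_rate >= 0.5) {
    stop("events must be sparse: event_rate * event_duration_mean / sampling_rate must be < 0.5",
         call. = FALSE)
  }
  structure(p, class = "sim_params")
}

#' Generate planted state topographies
#'
#' Draws `n_states` binary region-membership rows with exactly
#' `regions_per_state` active regions each and pairwise Jaccard overlap at
#' most `topography_overlap`. With zero allowed overlap the states partition a
#' shuffled region pool; otherwise rows are drawn by bounded rejection
#' sampling.
#'
#' @param n_regions,n_states,regions_per_state,topography_overlap see
#'   [sim_params()].
#' @param seed integer seed.
#' @param max_tries rejection-sampling bound per row.
#' @return `n_states x n_regions` binary matrix.
#' @export
make_topographies <- function(n_regions, n_states, regions_per_state,
                              topography_overlap = 0, seed = 1L,
                              max_tries = 5000L) {
  stopifnot(regions_per_state <= n_regions, n_states >= 1)
  topo <- matrix(0L, n_states, n_regions)
  with_rng(seed, {
    if (topography_overlap == 0) {
      if (n_states * regions_per_state > n_regions) {
        stop("infeasible overlap: zero-overlap states need n_states * regions_per_state <= n_regions",
             call. = FALSE)
      }
      pool <- sample.int(n_regions)
      for (s in seq_len(n_states)) {
        idx <- pool[((s - 1) * regions_per_state + 1):(s * regions_per_state)]
        topo[s, idx] <- 1L
      }
    } else {
      for (s in seq_len(n_states)) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          idx <- sample.int(n_regions, regions_per_state)
          cand <- integer(n_regions)
          cand[idx] <- 1L
          if (s == 1L || all(pairwise_jaccard(topo[seq_len(s - 1), , drop = FALSE], cand) <=
                               topography_overlap + 1e-12)) {
            topo[s, ] <- cand
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop("infeasible overlap: could not place state ", s,
               " within the overlap constraint after ", max_tries, " tries",
               call. = FALSE)
        }
      }
    }
  })
  rownames(topo) <- paste0("state_", seq_len(n_states))
  topo
}

# Jaccard overlap between each row of binary matrix `rows` and binary vector `v`.
pairwise_jaccard <- function(rows, v) {
  inter <- as.vector(rows %*% v)
  uni <- rowSums(rows) + sum(v) - inter
  ifelse(uni == 0, 0, inter / uni)
}

#' Planted state-transition matrix
#'
#' Uniform off-diagonal chain with extra diagonal mass:
#' `P = (1 - b) / K + b * I`, so every row sums to one and the diagonal is the
#' row maximum whenever `b > 0`.
#'
#' @param n_states number of states K.
#' @param self_transition_bias diagonal bias b in `[0, 1]`.
#' @return `K x K` row-stochastic matrix.
#' @export
make_planted_transition <- function(n_states, self_transition_bias = 0.1) {
  stopifnot(n_states >= 1, self_transition_bias >= 0, self_transition_bias <= 1)
  P <- matrix((1 - self_transition_bias) / n_states, n_states, n_states)
  diag(P) <- diag(P) + self_transition_bias
  P
}

#' Simulate one subject
#'
#' Places non-overlapping transient events (geometric durations, at least one
#' silent sample between events) on a Gaussian background, draws the event
#' state sequence from the planted Markov chain (uniform initial state), and
#' within each event adds `burst_amplitude` to every recruited member region
#' over the whole event. Recruitment of each member is Bernoulli with
#' `membership_recruitment_prob`, forced to at least one region per event.
#'
#' @param params a [sim_params()] object.
#' @param topographies planted `K x N` binary membership matrix.
#' @param planted_transition `K x K` row-stochastic matrix.
#' @param seed integer seed for this subject.
#' @param subject_id subject label.
#' @return list with `signals` (a [signal_set()]) and `truth` (state sequence,
#'   intervals, realized recruitment patterns).
#' @export
simulate_subject <- function(params, topographies, planted_transition,
                             seed = 1L, subject_id = "s01") {
  stopifnot(inherits(params, "sim_params"))
  K <- nrow(topographies)
  N <- params$n_regions
  stopifnot(ncol(topographies) == N, nrow(planted_transition) == K,
            ncol(planted_transition) == K)
  if (any(abs(rowSums(planted_transition) - 1) > 1e-12)) {
    stop("planted_transition rows must sum to 1", call. = FALSE)
  }
  T_len <- as.integer(round(params$duration * params$sampling_rate))

  with_rng(seed, {
    # background noise, unit SD
    if (params$noise_model == "white") {
      noise <- matrix(stats::rnorm(N * T_len), N, T_len)
    } else {
      phi <- params$ar_coef
      innov <- matrix(stats::rnorm(N * T_len), N, T_len)
      noise <- t(apply(innov, 1, function(e) as.numeric(stats::filter(e, phi, method = "recursive"))))
      noise <- noise * sqrt(1 - phi^2) # unit stationary SD
    }
    if (params$fixture_mode) {
      noise[noise > 2.9] <- 2.9
      noise[noise < -2.9] <- -2.9
    }

    n_events <- stats::rpois(1, params$event_rate * params$duration)
    starts <- ends <- integer(0)
    states <- integer(0)
    patterns <- matrix(0L, 0, N)
    if (n_events > 0) {
      m <- params$event_duration_mean
      dur <- stats::rgeom(n_events, prob = 1 / m) + 1L
      slack <- T_len - sum(dur) - (n_events - 1L)
      if (slack < 0) {
        stop("cannot place ", n_events, " non-overlapping events of total length ",
             sum(dur), " in ", T_len, " samples", call. = FALSE)
      }
      gaps <- as.integer(stats::rmultinom(1, slack, rep(1, n_events + 1L)))
      steps <- if (n_events > 1L) dur[-n_events] + 1L + gaps[2:n_events] else integer(0)
      starts <- cumsum(c(gaps[1], steps))
      ends <- starts + dur
      starts <- as.integer(starts)

      states <- integer(n_events)
      states[1] <- sample.int(K, 1)
      for (i in seq_len(n_events - 1L)) {
        states[i + 1L] <- sample.int(K, 1, prob = planted_transition[states[i], ])
      }

      patterns <- matrix(0L, n_events, N)
      for (i in seq_len(n_events)) {
        members <- which(topographies[states[i], ] == 1L)
        rec <- members[stats::runif(length(members)) < params$membership_recruitment_prob]
        if (length(rec) == 0) rec <- members[sample.int(length(members), 1)]
        patterns[i, rec] <- 1L
        cols <- (starts[i] + 1L):ends[i] # 0-based start -> 1-based columns
        if (params$fixture_mode) {
          # replace the background so the burst height is exact: an additive
          # burst on truncated noise can dip to amplitude - 2.9 and fall
          # below threshold after z-scoring
          noise[rec, cols] <- params$burst_amplitude
        } else {
          noise[rec, cols] <- noise[rec, cols] + params$burst_amplitude
        }
      }
    }
    labels <- if (N == 90) aal90_labels() else sprintf("R%03d", seq_len(N))
    list(
      signals = signal_set(noise, region_labels = labels,
                           sampling_rate = params$sampling_rate,
                           subject_id = subject_id),
      truth = list(
        state_sequence = states,
        intervals = data.frame(start = starts, end = ends,
                               subject_id = rep(subject_id, length(starts)),
                               stringsAsFactors = FALSE),
        patterns = patterns,
        seed = as.integer(seed)
      )
    )
  })
}

#' Simulate a cohort with shared planted structure
#'
#' All subjects share one topography matrix and one planted transition chain;
#' per-subject seeds are derived from the master seed with [split_seed()], so
#' a cohort is fully reproducible from `params`.
#'
#' @param params a [sim_params()] object.
#' @return list with `signals` (list of [signal_set()]) and `truth` (an object
#'   holding topographies, the planted chain, per-subject state sequences,
#'   intervals and realized patterns).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  topo <- make_topographies(params$n_regions, params$n_states,
                            params$regions_per_state,
                            params$topography_overlap,
                            seed = split_seed(params$seed, 0L))
  P <- make_planted_transition(params$n_states, params$self_transition_bias)
  ids <- sprintf("s%02d", seq_len(params$n_subjects))
  subs <- lapply(seq_len(params$n_subjects), function(i) {
    simulate_subject(params, topo, P, seed = split_seed(params$seed, i),
                     subject_id = ids[i])
  })
  truth <- list(
    topographies = topo,
    planted_transition = P,
    state_sequence = lapply(subs, function(s) s$truth$state_sequence),
    intervals = do.call(rbind, lapply(subs, function(s) s$truth$intervals)),
    patterns = do.call(rbind, lapply(subs, function(s) s$truth$patterns)),
    subject_ids = ids,
    seed = params$seed
  )
  names(truth$state_sequence) <- ids
  structure(list(signals = lapply(subs, `[[`, "signals"), truth = truth,
                 params = params),
            class = "av_cohort")
}
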