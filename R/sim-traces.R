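#' Construct a trace set
#'
#' Container for raw somatic and neuropil fluorescence of one session:
#' matrices of neurons x frames, per-neuron cell-type labels
#' (`"pyr"`/`"inh"`) and the imaging frame rate.
#'
#' @param F neurons x frames matrix of raw ROI fluorescence (a.u.).
#' @param Fneu neurons x frames matrix of neuropil fluorescence; must
#'   match `F` in shape.
#' @param celltype character/factor vector of length `nrow(F)` with
#'   levels `"pyr"` and `"inh"`.
#' @param frame_rate_hz imaging frame rate (Hz), positive.
#' @return an object of class `trace_set`.
#' @export
trace_set <- function(F, Fneu, celltype, frame_rate_hz) {
  F <- as.matrix(F); Fneu <- as.matrix(Fneu)
  assert_that(all(dim(F) == dim(Fneu)),
              "F and Fneu must have identical dimensions")
  assert_that(length(celltype) == nrow(F),
              "celltype must have one label per neuron")
  celltype <- factor(as.character(celltype), levels = c("pyr", "inh"))
  assert_that(!anyNA(celltype), "celltype labels must be 'pyr' or 'inh'")
  assert_that(is_scalar_number(frame_rate_hz) && frame_rate_hz > 0,
              "frame_rate_hz must be a positive scalar")
  structure(list(F = F, Fneu = Fneu, celltype = celltype,
                 frame_rate_hz = frame_rate_hz),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d neurons (%d inh) x %d frames @ %g Hz (%.1f s)\n",
              nrow(x$F), sum(x$celltype == "inh"), ncol(x$F),
              x$frame_rate_hz, ncol(x$F) / x$frame_rate_hz))
  invisible(x)
}

#' @export
dim.trace_set <- function(x) dim(x$F)

# Slow common signal shared across the population: white noise smoothed by
# a Gaussian kernel whose width implements a ~1 Hz low-pass cutoff, then
# standardized.  Drives pairwise correlations via per-neuron loadings.
lowpass_common_signal <- function(n_frames, frame_rate_hz, cutoff_hz = 1) {
  sigma_frames <- frame_rate_hz / (2 * pi * cutoff_hz)
  half <- max(1L, ceiling(4 * sigma_frames))
  kern <- stats::dnorm(seq(-half, half), sd = sigma_frames)
  kern <- kern / sum(kern)
  pad <- stats::rnorm(n_frames + 2 * half)
  sm <- stats::filter(pad, kern, sides = 2)
  sm <- as.numeric(sm[(half + 1):(half + n_frames)])
  as.numeric(scale(sm))
}

# Calcium transient kernel: instantaneous rise, single-exponential decay.
calcium_kernel <- function(tau_s, frame_rate_hz, length_s = 2) {
  t <- seq(0, length_s, by = 1 / frame_rate_hz)
  exp(-t / tau_s)
}

#' Simulate fluorescence traces for one session
#'
#' Generates raw somatic (`F`) and neuropil (`Fneu`) fluorescence from a
#' behavioral trial table and the mouse's ground-truth neural model. For
#' each neuron, activity in dF/F units is the sum of (i) stimulus-evoked
#' calcium transients (instantaneous rise, exponential decay) on trials
#' where the neuron is recruited, with recruitment drawn per trial from
#' [recruit_prob()] modulated by a per-trial shared excitability whose
#' per-neuron strength is the shared-gain loading (this co-modulation is
#' what sets pairwise ensemble correlations); (ii) a small loading on a
#' slow common signal shared across the population; and (iii) white
#' Gaussian noise. A fraction of neurons responds with negative-going
#' (inhibited) transients. Spontaneous (floor-level) recruitment also
#' occurs on catch trials at the sham stimulus time. The measured fluorescence is composed as
#' `F = F_true + ratio * Fneu`, so standard neuropil correction with the
#' same coefficient removes the contaminant in expectation.
#'
#' @param trials trial table with simulated behavior.
#' @param mouse a [ground_truth_mouse()].
#' @param cfg the session's [sim_config()].
#' @param seed integer seed.
#' @param n_neurons population size; drawn uniformly from
#'   `cfg$n_neurons_range` when `NULL`. Values outside the configured
#'   range are an error.
#' @return a list with elements `traces` (a [trace_set()]) and
#'   `recruitment` (trials x neurons matrix of ground-truth labels
#'   +1/-1/0, for parameter-recovery testing).
#' @export
simulate_traces <- function(trials, mouse, cfg, seed = NULL, n_neurons = NULL) {
  assert_that(all(!is.na(trials$outcome) | trials$timeout),
              "behavior must be simulated before traces")
  with_rng_seed(seed, {
    fr <- cfg$frame_rate_hz
    if (is.null(n_neurons)) {
      n_neurons <- sample(seq(cfg$n_neurons_range[1], cfg$n_neurons_range[2]), 1)
    }
    assert_that(n_neurons >= cfg$n_neurons_range[1] &&
                  n_neurons <= cfg$n_neurons_range[2],
                "n_neurons %d outside configured range [%d, %d]",
                n_neurons, cfg$n_neurons_range[1], cfg$n_neurons_range[2])

    n_frames <- ceiling((max(trials$stim_offset_s) + 12) * fr)
    t_frames <- (seq_len(n_frames) - 1) / fr

    n_inh <- round(n_neurons * cfg$interneuron_fraction)
    celltype <- c(rep("pyr", n_neurons - n_inh), rep("inh", n_inh))

    # per-neuron parameters jittered around the mouse-level means
    evoked_amp <- mouse$evoked_amp_gain *
      stats::rlnorm(n_neurons, meanlog = 0, sdlog = 0.3)
    latency <- pmax(0, mouse$latency_s + stats::rnorm(n_neurons, sd = 0.015))
    loading <- clamp(mouse$shared_gain_loading * stats::runif(n_neurons, 0.5, 1.5),
                     0, 1)
    sign <- ifelse(stats::runif(n_neurons) < mouse$inhibited_fraction, -1, 1)
    f0 <- stats::runif(n_neurons, 80, 120)
    fneu0 <- stats::runif(n_neurons, 30, 50)

    common <- lowpass_common_signal(n_frames, fr)
    kern <- calcium_kernel(mouse$calcium_tau_s, fr)

    detected <- !is.na(trials$outcome) & trials$outcome == "hit"
    stim_trial <- trials$trial_type == "go" & !trials$timeout
    eligible_trials <- which(stim_trial | trials$trial_type == "nogo")

    recruit <- matrix(0L, nrow = nrow(trials), ncol = n_neurons)
    p_rec <- recruit_prob(mouse, trials$amplitude_um, detected,
                          max_amplitude_um = max(cfg$amplitudes_um))
    # catch trials: spontaneous floor only; deliberately not scaled by
    # recruit_scale, which models a deficit of stimulus-evoked recruitment
    # while spontaneous dynamics stay intact
    p_rec[trials$trial_type == "nogo"] <- clamp(mouse$recruit_floor, 0, 1)
    p_rec[trials$timeout] <- 0

    amp_norm <- ifelse(is.na(trials$amplitude_um), 0.5,
                       trials$amplitude_um / max(cfg$amplitudes_um))
    gain_trial <- (0.5 + 0.5 * amp_norm) *
      ifelse(detected, mouse$detect_gain_factor, 1)

    # per-trial shared excitability: co-modulates recruitment across the
    # population; the strength of the modulation per neuron is its loading,
    # so shared_gain_loading directly controls pairwise ensemble
    # correlations of the trinary response vectors
    excitability <- stats::rnorm(nrow(trials))

    act <- matrix(0, nrow = n_neurons, ncol = n_frames)
    for (j in seq_len(n_neurons)) {
      p_j <- clamp(p_rec * (1 + loading[j] * excitability), 0, 1)
      rec <- stats::runif(nrow(trials)) < p_j
      rec[!(seq_len(nrow(trials)) %in% eligible_trials)] <- FALSE
      recruit[rec, j] <- sign[j]
      if (any(rec)) {
        onset_fr <- floor((trials$stim_onset_s[rec] + latency[j]) * fr) + 1
        amps <- sign[j] * evoked_amp[j] * gain_trial[rec] *
          stats::rlnorm(sum(rec), 0, 0.2)
        for (k in seq_along(onset_fr)) {
          idx <- onset_fr[k]:min(n_frames, onset_fr[k] + length(kern) - 1)
          act[j, idx] <- act[j, idx] + amps[k] * kern[seq_along(idx)]
        }
      }
    }

    noise <- matrix(stats::rnorm(n_neurons * n_frames, sd = mouse$baseline_noise_sd),
                    nrow = n_neurons)
    # additive slow common signal, modest relative to the per-frame noise
    # so that z-scoring does not saturate its contribution
    sig <- act + outer(0.05 * loading, common) + noise

    # neuropil channel: shares the common signal plus its own noise (both
    # scaled by the mouse's noise/loading levels, so a silent mouse has a
    # silent neuropil); the measured ROI trace adds ratio * Fneu so that
    # correction removes the contaminant in expectation
    neu_sig <- 0.15 * mean(loading) *
      matrix(rep(common, each = n_neurons), nrow = n_neurons) +
      matrix(stats::rnorm(n_neurons * n_frames,
                          sd = mouse$baseline_noise_sd / 3), nrow = n_neurons)
    Fneu <- fneu0 * (1 + neu_sig)
    F_true <- f0 * (1 + sig)
    F <- F_true + mouse$neuropil_ratio * Fneu

    list(traces = trace_set(F, Fneu, celltype, fr), recruitment = recruit)
  })
}

#' Simulate one complete session (behavior + imaging)
#'
#' Chains [simulate_trials()], [simulate_behavior()] and
#' [simulate_traces()] under one seed.
#'
#' @param cfg a [sim_config()].
#' @param mouse a [ground_truth_mouse()].
#' @param seed integer seed; sub-stages derive child seeds from it.
#' @param n_neurons optional fixed population size.
#' @return an object of class `synthetic_session`: list with `trials`,
#'   `traces`, and `ground_truth` (the mouse plus the trials x neurons
#'   ground-truth recruitment matrix).
#' @export
simulate_session <- function(cfg, mouse = wt_mouse(), seed = NULL,
                             n_neurons = NULL) {
  trials <- simulate_trials(cfg, seed = child_seed(seed, "trials"))
  trials <- simulate_behavior(trials, mouse, cfg,
                              seed = child_seed(seed, "behavior"))
  tr <- simulate_traces(trials, mouse, cfg,
                        seed = child_seed(seed, "traces"),
                        n_neurons = n_neurons)
  structure(list(trials = trials, traces = tr$traces,
                 ground_truth = list(mouse = mouse,
                                     recruitment = tr$recruitment)),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> group '%s': %d trials, %d neurons\n",
              x$ground_truth$mouse$group, nrow(x$trials), nrow(x$traces$F)))
  invisible(x)
}

#' Simulate a cohort of mice across groups
#'
#' @param cfg a [sim_config()] shared by all sessions.
#' @param groups named list of [ground_truth_mouse()] presets, one per
#'   group (default wild-type-like and hyposensitive-like).
#' @param n_per_group number of mice per group (> 0).
#' @param seed integer seed; each mouse gets a derived child seed, so the
#'   whole cohort is reproducible and mice are independent.
#' @param n_neurons optional fixed population size for every mouse.
#' @return a tibble with columns `mouse_id`, `group`, `session`
#'   (list-column of `synthetic_session`).
#' @export
simulate_cohort <- function(cfg, groups = list(wt = wt_mouse(),
                                               hypo = hypo_mouse()),
                            n_per_group = 5, seed = 1, n_neurons = NULL) {
  assert_that(length(groups) >= 1, "need at least one group spec")
  assert_that(n_per_group >= 1, "n_per_group must be at least 1 (empty cohort)")
  ids <- unlist(lapply(names(groups), function(g)
    paste0(g, "_", seq_len(n_per_group))))
  assert_that(!anyDuplicated(ids), "duplicate mouse ids")
  rows <- purrr::map2(
    rep(names(groups), each = n_per_group), ids,
    function(g, id) {
      tibble::tibble(
        mouse_id = id, group = g,
        session = list(simulate_session(cfg, groups[[g]],
                                        seed = child_seed(seed, id),
                                        n_neurons = n_neurons)))
    })
  dplyr::bind_rows(rows)
}
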