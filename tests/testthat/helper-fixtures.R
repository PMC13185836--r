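# Fixture builders shared across the suite.  Everything is generated in
# code under fixed seeds; no data files.

# Signal-free session: white-noise dF/F on a real trial layout, so the
# randomization test sees pure noise.  Returns the aligned tensor plus the
# pieces needed to classify recruitment.
null_session_fixture <- function(seed, n_trials = 40, n_neurons = 20) {
  cfg <- sim_config("testing", n_trials = n_trials,
                    n_neurons_range = c(n_neurons, n_neurons))
  trials <- simulate_trials(cfg, seed = seed)
  trials$outcome <- ifelse(trials$trial_type == "go", "miss", "cr")
  n_frames <- ceiling((max(trials$stim_offset_s) + 12) * cfg$frame_rate_hz)
  set.seed(seed + 999)
  d <- matrix(rnorm(n_neurons * n_frames), nrow = n_neurons)
  at <- align_trials(d, trials, cfg$frame_rate_hz)
  z <- recording_zscores(d, at)
  elig <- eligibility_mask(trials, n_frames, cfg$frame_rate_hz)
  nulls <- build_nulls(z, elig, seed = seed)
  list(cfg = cfg, trials = trials, dff = d, at = at, z = z,
       eligible = elig, nulls = nulls)
}

# Hand-built aligned tensor with controllable Hit/Miss separation: a mean
# shift of `effect` (in noise-SD units) is added to every neuron on the
# stimulation frames of Hit trials.  Fast fixture for decoding tests.
toy_tensor <- function(n_hit = 20, n_miss = 20, n_neurons = 10,
                       effect = 0, seed = 1, frame_rate_hz = 30.96,
                       prestim_effect = 0) {
  set.seed(seed)
  w <- list(pre = round(frame_rate_hz), stim = round(0.5 * frame_rate_hz),
            post = round(0.5 * frame_rate_hz), frame_rate_hz = frame_rate_hz)
  wlen <- w$pre + w$stim + w$post
  n_trials <- n_hit + n_miss
  outcome <- c(rep("hit", n_hit), rep("miss", n_miss))
  dff <- array(rnorm(n_trials * n_neurons * wlen), c(n_trials, n_neurons, wlen))
  stim_cols <- w$pre + seq_len(w$stim)
  pre_cols <- seq_len(w$pre)
  dff[outcome == "hit", , stim_cols] <- dff[outcome == "hit", , stim_cols] + effect
  if (prestim_effect != 0) {
    dff[outcome == "hit", , pre_cols] <- dff[outcome == "hit", , pre_cols] +
      prestim_effect
  }
  structure(list(
    z = dff, dff = dff,
    valid_mask = matrix(TRUE, n_trials, wlen),
    meta = tibble::tibble(
      trial_idx = seq_len(n_trials), trial_type = "go",
      amplitude_um = 6, outcome = outcome, detected = outcome == "hit",
      onset_frame = NA_integer_, first_lick_frame = NA_integer_,
      n_valid_stim = w$stim, included = TRUE),
    neurons = tibble::tibble(
      neuron = seq_len(n_neurons),
      celltype = factor(rep("pyr", n_neurons), levels = c("pyr", "inh")),
      mu = 0, sigma = 1, excluded = FALSE),
    window = w), class = "aligned_tensor")
}

# Minimal recruitment object around a labels matrix (trials x neurons).
toy_recruitment <- function(labels, trial_type = NULL, detected = NULL,
                            celltype = NULL, amplitude = NULL) {
  n_trials <- nrow(labels); n_neurons <- ncol(labels)
  structure(list(
    labels = labels,
    meta = tibble::tibble(
      trial_idx = seq_len(n_trials),
      trial_type = trial_type %||% rep("go", n_trials),
      amplitude_um = amplitude %||% rep(6, n_trials),
      outcome = NA_character_,
      detected = detected %||% rep(TRUE, n_trials),
      onset_frame = NA_integer_, first_lick_frame = NA_integer_,
      n_valid_stim = 15L, included = TRUE),
    neurons = tibble::tibble(
      neuron = seq_len(n_neurons),
      celltype = factor(celltype %||% rep("pyr", n_neurons),
                        levels = c("pyr", "inh")),
      mu = 0, sigma = 1, excluded = FALSE)), class = "recruitment")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
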