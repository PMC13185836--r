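#' Simulation configuration for a synthetic Go/No-Go imaging session
#'
#' Bundles the task-structure parameters of one simulated session:
#' trial counts, Go:No-Go ratio, stimulus amplitudes/frequency/duration,
#' response window, inter-trial-interval range, imaging frame rate and
#' population size. Defaults follow the two task phases: `training`
#' sessions use a single large-amplitude stimulus (15 µm, 40 Hz) with a
#' 75% Go fraction; `testing` sessions present six amplitudes between 2
#' and 12 µm at 10 Hz with a 90% Go fraction. Both phases default to 300
#' pseudorandomized trials.
#'
#' @param phase `"testing"` or `"training"`.
#' @param n_trials number of trials per session.
#' @param go_fraction fraction of Go trials, strictly inside (0, 1) except
#'   that 1 is accepted as a degenerate all-Go session.
#' @param amplitudes_um vector of stimulus amplitudes in micrometers;
#'   must be positive and is sorted internally.
#' @param stim_freq_hz vibration frequency (Hz).
#' @param stim_dur_s stimulus duration (s).
#' @param response_window_s response window after stimulus offset (s).
#' @param iti_range_s length-2 range of inter-trial intervals (s).
#' @param frame_rate_hz imaging frame rate (Hz).
#' @param n_neurons_range length-2 range for the simulated population size.
#' @param interneuron_fraction fraction of GABAergic interneurons.
#' @param timeout_rate probability that a Go trial is canceled by
#'   pre-stimulus licking (timeout).
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config("testing")
#' cfg$amplitudes_um
#' @export
sim_config <- function(phase = c("testing", "training"),
                       n_trials = 300L,
                       go_fraction = NULL,
                       amplitudes_um = NULL,
                       stim_freq_hz = NULL,
                       stim_dur_s = 0.5,
                       response_window_s = 2.0,
                       iti_range_s = c(5, 10),
                       frame_rate_hz = 30.96,
                       n_neurons_range = c(50L, 150L),
                       interneuron_fraction = 0.20,
                       timeout_rate = 0.02) {
  phase <- match.arg(phase)
  go_fraction <- go_fraction %||% if (phase == "training") 0.75 else 0.90
  amplitudes_um <- amplitudes_um %||%
    if (phase == "training") 15 else c(2, 4, 6, 8, 10, 12)
  stim_freq_hz <- stim_freq_hz %||% if (phase == "training") 40 else 10

  assert_that(length(amplitudes_um) >= 1 && all(amplitudes_um > 0),
              "amplitudes_um must be a non-empty vector of positive amplitudes")
  assert_that(is_scalar_number(n_trials) && n_trials > 0,
              "n_trials must be a positive count")
  assert_that(go_fraction > 0 && go_fraction <= 1,
              "go_fraction must lie in (0, 1]")
  assert_that(frame_rate_hz > 0, "frame_rate_hz must be positive")
  assert_that(length(iti_range_s) == 2 && iti_range_s[1] <= iti_range_s[2] &&
                iti_range_s[1] > 0, "iti_range_s must be an increasing positive range")
  assert_that(interneuron_fraction >= 0 && interneuron_fraction < 1,
              "interneuron_fraction must lie in [0, 1)")

  structure(list(
    phase = phase,
    n_trials = as.integer(n_trials),
    go_fraction = go_fraction,
    amplitudes_um = sort(unique(amplitudes_um)),
    stim_freq_hz = stim_freq_hz,
    stim_dur_s = stim_dur_s,
    response_window_s = response_window_s,
    iti_range_s = iti_range_s,
    frame_rate_hz = frame_rate_hz,
    n_neurons_range = as.integer(n_neurons_range),
    interneuron_fraction = interneuron_fraction,
    timeout_rate = timeout_rate
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %s phase: %d trials, %.0f%% Go, amplitudes {%s} um @ %g Hz\n",
              x$phase, x$n_trials, 100 * x$go_fraction,
              paste(x$amplitudes_um, collapse = ","), x$stim_freq_hz))
  cat(sprintf("  stim %gs + %gs response window; ITI %g-%g s; imaging %g Hz; %d-%d neurons (%.0f%% inh)\n",
              x$stim_dur_s, x$response_window_s, x$iti_range_s[1], x$iti_range_s[2],
              x$frame_rate_hz, x$n_neurons_range[1], x$n_neurons_range[2],
              100 * x$interneuron_fraction))
  invisible(x)
}

#' Ground-truth parameters of a simulated mouse
#'
#' Describes the latent behavioral and neural parameters from which a
#' synthetic session is generated: a logistic psychometric function
#' (threshold, slope, lapse), a fixed false-alarm rate, and the neural
#' response model (recruitment probabilities, evoked-transient gain,
#' response latency, shared-gain loading controlling ensemble
#' correlations, baseline noise, and the calcium-kernel decay constant).
#'
#' Recruitment probability for a neuron on a trial is
#' `recruit_floor + recruit_amp_gain * amp/max(amp) + recruit_detect_boost *
#' detected`, scaled by `recruit_scale` and clamped to \[0, 1\]; on catch
#' trials only the floor applies (spontaneous recruitment).
#'
#' @param group label for the simulated phenotype group.
#' @param threshold_um psychometric threshold (µm).
#' @param slope psychometric slope on the logit scale (per µm).
#' @param lapse_rate lapse probability (defaults to 0 so the generator and
#'   the lapse-free psychometric fitter share one model).
#' @param fa_rate false-alarm probability on No-Go trials.
#' @param recruit_floor,recruit_amp_gain,recruit_detect_boost,recruit_scale
#'   recruitment-probability model (see Details).
#' @param evoked_amp_gain mean evoked transient amplitude (dF/F units).
#' @param detect_gain_factor multiplicative gain on evoked amplitude for
#'   detected (Hit) trials.
#' @param latency_s mean response latency after stimulus onset (s).
#' @param shared_gain_loading ensemble-correlation strength in \[0, 1\]:
#'   scales both the per-trial shared excitability that co-modulates
#'   recruitment probabilities across neurons and the amplitude of the
#'   slow common trace signal.
#' @param baseline_noise_sd SD of per-frame Gaussian noise (dF/F units).
#' @param neuropil_ratio contamination coefficient used when composing the
#'   measured fluorescence from the neuropil channel.
#' @param calcium_tau_s single-exponential decay constant of the calcium
#'   kernel (s).
#' @param inhibited_fraction fraction of neurons whose stimulus response is
#'   a negative-going transient.
#' @return an object of class `ground_truth_mouse`.
#' @seealso [wt_mouse()], [hypo_mouse()]
#' @export
ground_truth_mouse <- function(group = "wt",
                               threshold_um = 4,
                               slope = 1.0,
                               lapse_rate = 0,
                               fa_rate = 0.12,
                               recruit_floor = 0.05,
                               recruit_amp_gain = 0.15,
                               recruit_detect_boost = 0.15,
                               recruit_scale = 1.0,
                               evoked_amp_gain = 0.8,
                               detect_gain_factor = 1.3,
                               latency_s = 0.05,
                               shared_gain_loading = 0.6,
                               baseline_noise_sd = 0.06,
                               neuropil_ratio = 0.7,
                               calcium_tau_s = 0.2,
                               inhibited_fraction = 0.15) {
  probs <- c(lapse_rate, fa_rate, recruit_floor, recruit_scale,
             interneuron = NA_real_)
  assert_that(all(c(lapse_rate, fa_rate) >= 0 & c(lapse_rate, fa_rate) <= 1),
              "lapse_rate and fa_rate must be probabilities")
  assert_that(calcium_tau_s > 0, "calcium_tau_s must be positive")
  assert_that(threshold_um > 0, "threshold_um must be positive")
  structure(list(
    group = group,
    threshold_um = threshold_um,
    slope = slope,
    lapse_rate = lapse_rate,
    fa_rate = fa_rate,
    recruit_floor = recruit_floor,
    recruit_amp_gain = recruit_amp_gain,
    recruit_detect_boost = recruit_detect_boost,
    recruit_scale = recruit_scale,
    evoked_amp_gain = evoked_amp_gain,
    detect_gain_factor = detect_gain_factor,
    latency_s = latency_s,
    shared_gain_loading = shared_gain_loading,
    baseline_noise_sd = baseline_noise_sd,
    neuropil_ratio = neuropil_ratio,
    calcium_tau_s = calcium_tau_s,
    inhibited_fraction = inhibited_fraction
  ), class = "ground_truth_mouse")
}

#' Preset: wild-type-like simulated mouse
#'
#' Threshold at 4 µm (the conventional average wild-type detection
#' threshold used downstream), no lapse, moderate false-alarm rate.
#'
#' @param ... overrides forwarded to [ground_truth_mouse()].
#' @return a `ground_truth_mouse`.
#' @export
wt_mouse <- function(...) {
  ground_truth_mouse(group = "wt", ...)
}

#' Preset: hyposensitive-like simulated mouse
#'
#' Relative to [wt_mouse()]: detection threshold shifted up by 4 µm,
#' recruitment probability and detected-trial evoked gain scaled by 0.6,
#' response latency lengthened by 60 ms, and shared-gain loading halved.
#' The preset reproduces the directional contrasts of a hyposensitive
#' phenotype (higher threshold, weaker recruitment, lower SNR, slower and
#' less correlated ensemble responses), not exact magnitudes.
#'
#' @param ... overrides forwarded to [ground_truth_mouse()].
#' @return a `ground_truth_mouse`.
#' @export
hypo_mouse <- function(...) {
  args <- list(
    group = "hypo",
    threshold_um = 8,
    recruit_scale = 0.6,
    evoked_amp_gain = 0.8 * 0.6,
    latency_s = 0.05 + 0.06,
    shared_gain_loading = 0.6 * 0.5
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(ground_truth_mouse, args)
}

#' Recruitment probability of the generative model
#'
#' @param mouse a `ground_truth_mouse`.
#' @param amplitude_um stimulus amplitude (µm); `NA` or 0 for catch trials.
#' @param detected logical, whether the trial was detected (Hit).
#' @param max_amplitude_um normalization constant for the amplitude term.
#' @return probability in \[0, 1\], vectorized over inputs.
#' @export
recruit_prob <- function(mouse, amplitude_um, detected,
                         max_amplitude_um = 12) {
  amp <- ifelse(is.na(amplitude_um), 0, amplitude_um)
  p <- mouse$recruit_floor +
    mouse$recruit_amp_gain * amp / max_amplitude_um +
    mouse$recruit_detect_boost * as.numeric(detected)
  clamp(mouse$recruit_scale * p, 0, 1)
}
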