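#' Generate a pseudorandomized trial sequence
#'
#' Lays out one session of Go and No-Go (catch) trials: trial types are
#' pseudorandomly ordered, stimulus amplitudes are balanced across Go
#' trials (counts differ by at most one), and onset times accrue from
#' uniformly drawn inter-trial intervals. No-Go trials carry the scheduled
#' (sham) stimulus time so that downstream catch-trial windows can be
#' placed, but no stimulus amplitude.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; the sequence is reproducible given
#'   `cfg` + `seed`.
#' @return a tibble with one row per trial and columns `trial_idx`,
#'   `trial_type` (`"go"`/`"nogo"`), `amplitude_um` (`NA` on No-Go),
#'   `freq_hz`, `stim_onset_s`, `stim_offset_s`, `first_lick_s` (`NA`
#'   until behavior is simulated), `outcome` (`NA`), `timeout` (`FALSE`).
#' @examples
#' trials <- simulate_trials(sim_config("testing"), seed = 1)
#' table(trials$trial_type)
#' @export
simulate_trials <- function(cfg, seed = NULL) {
  assert_that(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  with_rng_seed(seed, {
    n <- cfg$n_trials
    n_go <- round(n * cfg$go_fraction)
    n_nogo <- n - n_go
    # balanced amplitude assignment: repeat the sorted list, so per-session
    # counts per amplitude differ by at most one
    amps <- rep_len(cfg$amplitudes_um, n_go)
    amps <- amps[sample.int(n_go)]
    type <- c(rep("go", n_go), rep("nogo", n_nogo))
    ord <- sample.int(n)
    type <- type[ord]
    amplitude <- rep(NA_real_, n)
    amplitude[type == "go"] <- amps

    iti <- stats::runif(n, cfg$iti_range_s[1], cfg$iti_range_s[2])
    # leave a quiet lead-in (>= 12 s) so baseline estimation and the 1-s
    # pre-stimulus window are always available
    onset <- 12 + cumsum(iti + cfg$stim_dur_s + cfg$response_window_s) -
      (cfg$stim_dur_s + cfg$response_window_s)

    tibble::tibble(
      trial_idx = seq_len(n),
      trial_type = type,
      amplitude_um = amplitude,
      freq_hz = cfg$stim_freq_hz,
      stim_onset_s = onset,
      stim_offset_s = onset + cfg$stim_dur_s,
      first_lick_s = NA_real_,
      outcome = NA_character_,
      timeout = FALSE
    )
  })
}

#' Simulate behavioral outcomes on a trial table
#'
#' Fills the `outcome`, `first_lick_s` and `timeout` columns from the
#' mouse's latent psychometric function. On Go trials the lick
#' probability is `(1 - lapse) * plogis(slope * (amp - threshold))`;
#' a lick yields a Hit, otherwise a Miss. No-Go trials become False
#' Alarms with probability `fa_rate`, else Correct Rejections. A small
#' fraction of Go trials is canceled by pre-stimulus licking (timeout);
#' these keep `outcome = NA` and are excluded from rate denominators
#' downstream. First-lick times are drawn uniformly between 150 ms after
#' onset and the end of the response window, so some first licks fall
#' within the stimulation window (as in real sessions, where they mask
#' late stimulus frames).
#'
#' @param trials a trial table from [simulate_trials()].
#' @param mouse a [ground_truth_mouse()].
#' @param cfg the [sim_config()] used to generate `trials`.
#' @param seed integer seed.
#' @return the trial table with behavior columns filled.
#' @export
simulate_behavior <- function(trials, mouse, cfg, seed = NULL) {
  assert_that(inherits(mouse, "ground_truth_mouse"),
              "mouse must be a ground_truth_mouse")
  with_rng_seed(seed, {
    n <- nrow(trials)
    is_go <- trials$trial_type == "go"
    out <- trials

    timeout <- is_go & stats::runif(n) < cfg$timeout_rate
    out$timeout <- timeout

    p_lick <- (1 - mouse$lapse_rate) *
      stats::plogis(mouse$slope * (trials$amplitude_um - mouse$threshold_um))
    lick <- rep(FALSE, n)
    lick[is_go] <- stats::runif(sum(is_go)) < p_lick[is_go]
    lick[timeout] <- FALSE

    fa <- !is_go & stats::runif(n) < mouse$fa_rate

    out$outcome[is_go & !timeout] <- ifelse(lick[is_go & !timeout], "hit", "miss")
    out$outcome[!is_go] <- ifelse(fa[!is_go], "fa", "cr")

    licked <- lick | fa
    rt_max <- cfg$stim_dur_s + cfg$response_window_s
    out$first_lick_s[licked] <- trials$stim_onset_s[licked] +
      stats::runif(sum(licked), 0.15, rt_max)
    out
  })
}
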