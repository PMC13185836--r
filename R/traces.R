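#' Neuropil correction
#'
#' Subtracts a scaled neuropil signal from each ROI trace:
#' `F_corrected = F - coef * Fneu` with the conventional coefficient 0.7.
#'
#' @param F neurons x frames matrix (or numeric vector) of ROI
#'   fluorescence.
#' @param Fneu matching matrix/vector of neuropil fluorescence.
#' @param coef contamination coefficient.
#' @return corrected fluorescence, same shape as `F`. Negative values are
#'   permitted (the correction can undershoot).
#' @examples
#' neuropil_correct(100, 10) # 93
#' @export
neuropil_correct <- function(F, Fneu, coef = 0.7) {
  assert_that(length(F) == length(Fneu) &&
                identical(dim(F), dim(Fneu)),
              "F and Fneu must have identical shapes")
  F - coef * Fneu
}

#' Baseline fluorescence from the quietest 10-s window
#'
#' For each neuron, slides a 10-s window (stride one frame) along the
#' recording and takes the mean fluorescence of the window with the
#' lowest standard deviation; ties go to the earliest window.
#'
#' @param x numeric vector (one trace) or neurons x frames matrix.
#' @param frame_rate_hz imaging frame rate (Hz).
#' @param window_s window length in seconds.
#' @return scalar baseline (vector input) or one baseline per neuron
#'   (matrix input).
#' @export
baseline_f <- function(x, frame_rate_hz, window_s = 10) {
  if (is.matrix(x)) {
    return(apply(x, 1, baseline_f, frame_rate_hz = frame_rate_hz,
                 window_s = window_s))
  }
  w <- round(window_s * frame_rate_hz)
  n <- length(x)
  assert_that(n >= w, "recording shorter than the %g-s baseline window", window_s)
  # running sums give O(n) window means and SDs
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n - w + 1)
  s <- cs[i + w] - cs[i]
  s2 <- cs2[i + w] - cs2[i]
  v <- pmax(0, s2 / w - (s / w)^2)
  # round to kill floating jitter so exact ties resolve to the earliest
  best <- which.min(signif(v, 12))
  s[best] / w
}

#' Relative fluorescence change (dF/F)
#'
#' @param F_corr neuropil-corrected fluorescence (vector or neurons x
#'   frames matrix).
#' @param baseline per-neuron baseline from [baseline_f()]; must be
#'   positive. Neurons with non-positive baselines are excluded: their
#'   rows are returned as `NA` and their indices recorded in the
#'   `excluded` attribute (with a message).
#' @return dF/F of the same shape as `F_corr`.
#' @export
dff <- function(F_corr, baseline) {
  if (!is.matrix(F_corr)) {
    assert_that(length(baseline) == 1, "one baseline per trace")
    if (baseline <= 0) stopf("non-positive baseline; neuron must be excluded")
    return((F_corr - baseline) / baseline)
  }
  assert_that(length(baseline) == nrow(F_corr),
              "need one baseline per neuron")
  bad <- which(baseline <= 0)
  out <- (F_corr - baseline) / baseline
  if (length(bad)) {
    out[bad, ] <- NA_real_
    message(sprintf("dff: excluded %d neuron(s) with non-positive baseline", length(bad)))
    attr(out, "excluded") <- bad
  }
  out
}

window_frames <- function(frame_rate_hz, pre_s = 1, stim_s = 0.5, post_s = 0.5) {
  list(pre = round(pre_s * frame_rate_hz),
       stim = round(stim_s * frame_rate_hz),
       post = round(post_s * frame_rate_hz))
}

#' Align dF/F traces to stimulus onsets and z-score
#'
#' Cuts a window (1 s pre-stimulus, 0.5 s stimulation, 0.5 s post) around
#' every trial's stimulus onset (the scheduled sham onset on catch
#' trials) and z-scores each neuron using the mean and SD of its pooled
#' 1-s pre-stimulus frames across all included trials:
#' `z(t) = (dFF(t) - mu_prestim) / sigma_prestim`. Stimulus-specific
#' statistics must not include movement-related activity, so every frame
#' from the trial's first lick onward is marked invalid in `valid_mask`.
#'
#' The onset frame is the first frame at or after the stimulus onset time
#' (0-based frames at `t = f / frame_rate`). At 30.96 Hz the window is
#' 31 + 15 + 15 = 61 frames. Trials canceled by timeout are dropped.
#' Trials with fewer than `min_valid` valid stimulation frames remain in
#' the tensor but are flagged excluded; neurons with zero pre-stimulus SD
#' are flagged constant and excluded.
#'
#' @param dff_mat neurons x frames dF/F matrix.
#' @param trials trial table with behavior.
#' @param frame_rate_hz imaging frame rate (Hz).
#' @param celltype optional per-neuron labels carried into the result.
#' @param pre_s,stim_s,post_s window spans (s).
#' @param min_valid minimum valid stimulation frames for a trial to be
#'   usable in stimulus-window statistics.
#' @return an object of class `aligned_tensor`: list with `z` and `dff`
#'   (trials x neurons x frames arrays), `valid_mask` (trials x frames),
#'   `meta` (per-trial tibble: `trial_idx`, `trial_type`, `amplitude_um`,
#'   `outcome`, `detected`, `onset_frame`, `first_lick_frame`,
#'   `n_valid_stim`, `included`), `neurons` (per-neuron tibble with
#'   `mu`, `sigma`, `excluded`, `celltype`), `window` (frame counts and
#'   frame rate).
#' @export
align_trials <- function(dff_mat, trials, frame_rate_hz, celltype = NULL,
                         pre_s = 1, stim_s = 0.5, post_s = 0.5,
                         min_valid = 2) {
  w <- window_frames(frame_rate_hz, pre_s, stim_s, post_s)
  wlen <- w$pre + w$stim + w$post
  n_neurons <- nrow(dff_mat)
  n_frames <- ncol(dff_mat)

  keep <- !trials$timeout
  tr <- trials[keep, ]
  eps <- 1e-9
  onset_frame <- ceiling(tr$stim_onset_s * frame_rate_hz - eps) # 0-based
  assert_that(all(onset_frame - w$pre >= 0),
              "every trial onset must be at least %g s after recording start", pre_s)
  assert_that(all(onset_frame + w$stim + w$post <= n_frames),
              "recording ends before the last trial window")

  n_trials <- nrow(tr)
  z <- array(NA_real_, dim = c(n_trials, n_neurons, wlen))
  dffw <- array(NA_real_, dim = c(n_trials, n_neurons, wlen))
  pre_idx <- matrix(NA_integer_, n_trials, w$pre)
  for (t in seq_len(n_trials)) {
    idx <- (onset_frame[t] - w$pre):(onset_frame[t] + w$stim + w$post - 1) + 1L
    dffw[t, , ] <- dff_mat[, idx, drop = FALSE]
    pre_idx[t, ] <- idx[seq_len(w$pre)]
  }

  # pooled pre-stimulus moments per neuron, across all included trials
  pre_cols <- as.vector(pre_idx)
  mu <- rowMeans(dff_mat[, pre_cols, drop = FALSE])
  sigma <- apply(dff_mat[, pre_cols, drop = FALSE], 1, stats::sd)
  excluded_neuron <- !is.finite(sigma) | sigma == 0 | !is.finite(mu)
  if (any(excluded_neuron)) {
    message(sprintf("align_trials: %d neuron(s) flagged constant/invalid",
                    sum(excluded_neuron)))
  }
  sigma_safe <- ifelse(excluded_neuron, NA_real_, sigma)
  for (j in seq_len(n_neurons)) {
    z[, j, ] <- (dffw[, j, ] - mu[j]) / sigma_safe[j]
  }

  # first-lick masking: frames from the lick frame onward are invalid
  valid <- matrix(TRUE, n_trials, wlen)
  lick_frame <- rep(NA_integer_, n_trials)
  rel_lick <- ceiling((tr$first_lick_s - tr$stim_onset_s) * frame_rate_hz - eps)
  for (t in seq_len(n_trials)) {
    if (!is.na(rel_lick[t]) && rel_lick[t] < w$stim + w$post) {
      start <- max(0L, rel_lick[t])
      valid[t, (w$pre + start + 1L):wlen] <- FALSE
      lick_frame[t] <- start
    }
  }
  stim_cols <- w$pre + seq_len(w$stim)
  n_valid_stim <- rowSums(valid[, stim_cols, drop = FALSE])
  included <- n_valid_stim >= min_valid
  if (any(!included)) {
    message(sprintf("align_trials: %d trial(s) excluded (< %d valid stimulation frames)",
                    sum(!included), min_valid))
  }

  if (is.null(celltype)) celltype <- rep("pyr", n_neurons)
  structure(list(
    z = z,
    dff = dffw,
    valid_mask = valid,
    meta = tibble::tibble(
      trial_idx = tr$trial_idx,
      trial_type = tr$trial_type,
      amplitude_um = tr$amplitude_um,
      outcome = tr$outcome,
      detected = !is.na(tr$outcome) & tr$outcome == "hit",
      onset_frame = onset_frame,
      first_lick_frame = lick_frame,
      n_valid_stim = n_valid_stim,
      included = included),
    neurons = tibble::tibble(
      neuron = seq_len(n_neurons),
      celltype = factor(as.character(celltype), levels = c("pyr", "inh")),
      mu = mu, sigma = sigma, excluded = excluded_neuron),
    window = list(pre = w$pre, stim = w$stim, post = w$post,
                  frame_rate_hz = frame_rate_hz)
  ), class = "aligned_tensor")
}

#' @export
print.aligned_tensor <- function(x, ...) {
  cat(sprintf("<aligned_tensor> %d trials x %d neurons x %d frames (pre %d / stim %d / post %d) @ %g Hz\n",
              dim(x$z)[1], dim(x$z)[2], dim(x$z)[3],
              x$window$pre, x$window$stim, x$window$post,
              x$window$frame_rate_hz))
  cat(sprintf("  %d trials included; %d neurons excluded\n",
              sum(x$meta$included), sum(x$neurons$excluded)))
  invisible(x)
}

# Column indices of the stimulation window inside the aligned window.
stim_columns <- function(at) at$window$pre + seq_len(at$window$stim)

#' Valid stimulation-window z-scores of one trial and neuron
#'
#' Returns only frames before the trial's first lick; this accessor is
#' the single gate through which stimulus-window statistics read the
#' tensor, so masked frames can never leak into downstream analyses.
#'
#' @param at an `aligned_tensor`.
#' @param trial,neuron indices into the tensor.
#' @return numeric vector of valid stimulation-window z values (possibly
#'   empty).
#' @export
stim_z <- function(at, trial, neuron) {
  cols <- stim_columns(at)
  ok <- at$valid_mask[trial, cols]
  at$z[trial, neuron, cols][ok]
}

#' Per-trial mean stimulation-window activity
#'
#' @param at an `aligned_tensor`.
#' @return trials x neurons matrix of mean z over valid stimulation
#'   frames (`NA` for excluded trials/neurons).
#' @export
trial_mean_stim_z <- function(at) {
  cols <- stim_columns(at)
  n_trials <- dim(at$z)[1]; n_neurons <- dim(at$z)[2]
  out <- matrix(NA_real_, n_trials, n_neurons)
  for (t in seq_len(n_trials)) {
    if (!at$meta$included[t]) next
    ok <- at$valid_mask[t, cols]
    out[t, ] <- rowMeans(at$z[t, , cols, drop = FALSE][, , ok, drop = FALSE],
                         dims = 2)
  }
  out[, at$neurons$excluded] <- NA_real_
  out
}

#' Savitzky-Golay smoothing for display
#'
#' Least-squares polynomial smoothing with the conventional
#' window-of-10-frames, order-3 configuration. Display only: all
#' quantitative analyses in this package operate on raw traces. Edge
#' frames are smoothed by evaluating the polynomial fitted to the
#' nearest full window. Even window lengths are supported by centering
#' the window at offsets `-w/2 ... w/2 - 1`.
#'
#' @param x numeric trace.
#' @param window window length in frames.
#' @param order polynomial order (must be < window).
#' @return smoothed trace, same length; traces shorter than the window
#'   are returned unchanged with a warning.
#' @export
savgol_smooth <- function(x, window = 10, order = 3) {
  n <- length(x)
  if (n < window) {
    warning("trace shorter than smoothing window; returning unsmoothed")
    return(x)
  }
  assert_that(order < window, "polynomial order must be below window length")
  left <- window %/% 2
  right <- window - left - 1L
  offs <- seq(-left, right)
  A <- outer(offs, 0:order, `^`)
  # projection rows: coefficient estimates evaluated at each offset
  H <- A %*% solve(crossprod(A), t(A))
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i - 1 < left) {
      win <- seq_len(window); pos <- i
    } else if (n - i < right) {
      win <- (n - window + 1):n; pos <- i - (n - window)
    } else {
      win <- (i - left):(i + right); pos <- left + 1L
    }
    out[i] <- H[pos, ] %*% x[win]
  }
  out
}
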