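#' Full-recording z-scores
#'
#' Applies the aligned tensor's per-neuron pre-stimulus mean and SD to
#' the whole dF/F recording, producing the z-scored traces from which
#' null distributions are sampled.
#'
#' @param dff_mat neurons x frames dF/F matrix.
#' @param at the `aligned_tensor` holding each neuron's `mu`/`sigma`.
#' @return neurons x frames matrix of z-scores (`NA` rows for excluded
#'   neurons).
#' @export
recording_zscores <- function(dff_mat, at) {
  sigma <- ifelse(at$neurons$excluded, NA_real_, at$neurons$sigma)
  (dff_mat - at$neurons$mu) / sigma
}

#' Frame eligibility for null sampling
#'
#' Marks frames usable for the null distribution of the randomization
#' test: everything except stimulation periods (onset to offset of every
#' stimulus trial) and reward periods (the response window following the
#' stimulus on rewarded trials).
#'
#' @param trials trial table with behavior.
#' @param n_frames number of frames in the recording.
#' @param frame_rate_hz imaging frame rate (Hz).
#' @param response_window_s reward-consumption window excluded after the
#'   stimulus on Hit trials (s).
#' @return logical vector of length `n_frames`; `TRUE` = eligible.
#' @export
eligibility_mask <- function(trials, n_frames, frame_rate_hz,
                             response_window_s = 2) {
  mask <- rep(TRUE, n_frames)
  drop_span <- function(from_s, to_s) {
    a <- max(1L, floor(from_s * frame_rate_hz) + 1L)
    b <- min(n_frames, ceiling(to_s * frame_rate_hz))
    if (a <= b) mask[a:b] <<- FALSE
  }
  stim <- trials$trial_type == "go" & !trials$timeout
  for (i in which(stim)) {
    drop_span(trials$stim_onset_s[i], trials$stim_offset_s[i])
    if (!is.na(trials$outcome[i]) && trials$outcome[i] == "hit") {
      drop_span(trials$stim_offset_s[i],
                trials$stim_offset_s[i] + response_window_s)
    }
  }
  mask
}

#' Null distribution for the stimulus-recruitment randomization test
#'
#' Samples z-score values at randomly selected eligible time points of
#' the recording (by default 1,999 points, without replacement) and
#' stores the percentiles against which stimulus-window percentiles are
#' compared: the 95th for activation and, under the symmetric default
#' rule, the 5th for inhibition.
#'
#' @param z numeric vector: one neuron's full-recording z-scores.
#' @param eligible logical eligibility mask from [eligibility_mask()].
#' @param n sample size (1,999 by default).
#' @param seed integer seed.
#' @return an object of class `null_distribution`: list with `values`,
#'   `p95`, `p05`, `n`, and `with_replacement` (TRUE, with a flag, when
#'   fewer than `n` frames were eligible).
#' @export
build_null <- function(z, eligible, n = 1999, seed = NULL) {
  pool <- which(eligible & !is.na(z))
  assert_that(length(pool) > 0, "no eligible frames for the null distribution")
  with_replacement <- length(pool) < n
  idx <- with_rng_seed(seed, {
    if (with_replacement) sample(pool, n, replace = TRUE)
    else sample(pool, n)
  })
  v <- z[idx]
  structure(list(values = v,
                 p95 = unname(stats::quantile(v, 0.95)),
                 p05 = unname(stats::quantile(v, 0.05)),
                 n = n,
                 with_replacement = with_replacement),
            class = "null_distribution")
}

#' Null distributions for every neuron of a session
#'
#' One null per neuron per session (default rule): applies [build_null()]
#' to each row of the full-recording z-score matrix, deriving one child
#' seed per neuron.
#'
#' @param z_mat neurons x frames z-score matrix.
#' @param eligible eligibility mask from [eligibility_mask()].
#' @param n,seed as in [build_null()].
#' @return list of `null_distribution`s (`NULL` for all-`NA` neurons).
#' @export
build_nulls <- function(z_mat, eligible, n = 1999, seed = NULL) {
  lapply(seq_len(nrow(z_mat)), function(j)
    if (all(is.na(z_mat[j, ]))) NULL
    else build_null(z_mat[j, ], eligible, n = n,
                    seed = if (is.null(seed)) NULL else child_seed(seed, j)))
}

# Trial-level label from stimulus-window percentiles vs the null.
classify_one <- function(stim_vals, null, act_pct = 0.85, inh_pct = 0.10,
                         literal_inhibition = FALSE) {
  if (length(stim_vals) < 2) return(NA_integer_)
  p_act <- unname(stats::quantile(stim_vals, act_pct))
  p_inh <- unname(stats::quantile(stim_vals, inh_pct))
  lo_ref <- if (literal_inhibition) null$p95 else null$p05
  act <- p_act > null$p95
  inh <- p_inh < lo_ref
  if (act && inh) {
    exc_act <- p_act - null$p95
    exc_inh <- lo_ref - p_inh
    if (exc_act > exc_inh) return(1L)
    if (exc_inh > exc_act) return(-1L)
    return(0L)
  }
  if (act) return(1L)
  if (inh) return(-1L)
  0L
}

#' Per-trial stimulus-recruitment classification
#'
#' The percentile randomization test: for each trial and neuron, the
#' 85th percentile of the z-score over valid stimulation frames (before
#' the first lick) is compared against the 95th percentile of the
#' neuron's null distribution; exceeding it classifies the neuron as
#' stimulus-activated (+1) on that trial. Inhibition compares the 10th
#' stimulus percentile against the low tail of the null: the symmetric
#' default uses the 5th null percentile; `literal_inhibition = TRUE`
#' compares against the 95th null percentile instead (the alternative
#' reading of the rule, kept behind a flag because it labels nearly
#' every neuron-trial inhibited). If both rules fire, the larger
#' percentile exceedance wins; exact ties give 0.
#'
#' @param at an `aligned_tensor`.
#' @param nulls list of per-neuron `null_distribution`s (from
#'   [build_nulls()] via [session_responses()], or built manually).
#' @param act_pct,inh_pct stimulus-window percentiles (0.85 / 0.10).
#' @param literal_inhibition use the literal asymmetric comparator.
#' @return an object of class `recruitment`: list with `labels`
#'   (trials x neurons integer matrix in \{-1, 0, +1\}, `NA` where a
#'   trial/neuron is excluded), `meta` and `neurons` copied from the
#'   tensor.
#' @export
classify_recruitment <- function(at, nulls, act_pct = 0.85, inh_pct = 0.10,
                                 literal_inhibition = FALSE) {
  n_trials <- dim(at$z)[1]; n_neurons <- dim(at$z)[2]
  labels <- matrix(NA_integer_, n_trials, n_neurons)
  for (t in which(at$meta$included)) {
    for (j in which(!at$neurons$excluded)) {
      if (is.null(nulls[[j]])) next
      labels[t, j] <- classify_one(stim_z(at, t, j), nulls[[j]],
                                   act_pct, inh_pct, literal_inhibition)
    }
  }
  structure(list(labels = labels, meta = at$meta, neurons = at$neurons),
            class = "recruitment")
}

#' @export
print.recruitment <- function(x, ...) {
  ok <- !is.na(x$labels)
  cat(sprintf("<recruitment> %d trials x %d neurons; activated %.1f%%, inhibited %.1f%% of neuron-trials\n",
              nrow(x$labels), ncol(x$labels),
              100 * mean(x$labels[ok] == 1), 100 * mean(x$labels[ok] == -1)))
  invisible(x)
}

#' Tidy per-trial recruited fractions
#'
#' For every included trial and cell type, the fraction of that type's
#' neurons recruited (activated or inhibited; or each side separately).
#'
#' @param rec a `recruitment`.
#' @return tibble with `trial_idx`, `trial_type`, `amplitude_um`,
#'   `detected`, `celltype`, `n_neurons`, `frac_recruited`,
#'   `frac_activated`, `frac_inhibited`.
#' @export
recruitment_fractions <- function(rec) {
  meta <- rec$meta
  out <- list()
  for (ct in levels(rec$neurons$celltype)) {
    cols <- which(rec$neurons$celltype == ct & !rec$neurons$excluded)
    if (!length(cols)) next
    lab <- rec$labels[, cols, drop = FALSE]
    out[[ct]] <- tibble::tibble(
      trial_idx = meta$trial_idx,
      trial_type = meta$trial_type,
      amplitude_um = meta$amplitude_um,
      detected = meta$detected,
      celltype = ct,
      n_neurons = length(cols),
      frac_recruited = rowMeans(lab != 0),
      frac_activated = rowMeans(lab == 1),
      frac_inhibited = rowMeans(lab == -1))
  }
  dplyr::bind_rows(out) |>
    dplyr::filter(!is.na(.data$frac_recruited)) |>
    dplyr::arrange(.data$trial_idx)
}

#' Condition-level recruitment proportions
#'
#' Averages per-trial recruited fractions over trials within each
#' condition (amplitude x detected x trial type x cell type), and
#' reports detected-minus-non-detected differences per amplitude.
#'
#' @param rec a `recruitment`.
#' @return list with `by_condition` (tibble of condition means; empty
#'   conditions are simply absent) and `detected_contrast` (per
#'   amplitude and cell type, mean detected minus mean non-detected
#'   fraction, `NA` when one side is absent).
#' @export
recruitment_proportions <- function(rec) {
  fr <- recruitment_fractions(rec)
  by_condition <- fr |>
    dplyr::group_by(.data$trial_type, .data$amplitude_um, .data$detected,
                    .data$celltype) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     frac_recruited = mean(.data$frac_recruited),
                     frac_activated = mean(.data$frac_activated),
                     frac_inhibited = mean(.data$frac_inhibited),
                     .groups = "drop")
  go <- dplyr::filter(by_condition, .data$trial_type == "go")
  detected_contrast <- go |>
    dplyr::select("amplitude_um", "detected", "celltype", "frac_recruited") |>
    tidyr::pivot_wider(names_from = "detected", values_from = "frac_recruited",
                       names_prefix = "det_")
  for (col in c("det_TRUE", "det_FALSE")) {
    if (!col %in% names(detected_contrast)) detected_contrast[[col]] <- NA_real_
  }
  detected_contrast$contrast <-
    detected_contrast$det_TRUE - detected_contrast$det_FALSE
  list(by_condition = by_condition, detected_contrast = detected_contrast)
}

#' Peak response amplitude and delay of recruited neuron-trials
#'
#' For every recruited neuron-trial, the peak is the maximum (activated)
#' or minimum (inhibited) z-score over valid stimulation frames, and the
#' delay is the number of frames from stimulus onset to that peak.
#'
#' @param at the `aligned_tensor` the labels were computed from.
#' @param rec the matching `recruitment`.
#' @return tibble with `trial_idx`, `neuron`, `celltype`, `label`,
#'   `peak_z`, `delay_frames` (0-based from onset), `delay_ms`.
#' @export
peak_metrics <- function(at, rec) {
  cols <- stim_columns(at)
  fr <- at$window$frame_rate_hz
  rows <- list()
  hits <- which(!is.na(rec$labels) & rec$labels != 0, arr.ind = TRUE)
  if (nrow(hits)) {
    for (k in seq_len(nrow(hits))) {
      t <- hits[k, 1]; j <- hits[k, 2]
      ok <- at$valid_mask[t, cols]
      if (!any(ok)) next
      vals <- at$z[t, j, cols]
      lab <- rec$labels[t, j]
      idx_valid <- which(ok)
      pk <- if (lab == 1) idx_valid[which.max(vals[idx_valid])]
            else idx_valid[which.min(vals[idx_valid])]
      rows[[length(rows) + 1]] <- tibble::tibble(
        trial_idx = rec$meta$trial_idx[t],
        neuron = j,
        celltype = as.character(rec$neurons$celltype[j]),
        label = lab,
        peak_z = vals[pk],
        delay_frames = pk - 1L,
        delay_ms = 1000 * (pk - 1L) / fr)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(trial_idx = integer(), neuron = integer(),
                          celltype = character(), label = integer(),
                          peak_z = numeric(), delay_frames = integer(),
                          delay_ms = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Single-neuron detection sensitivity (d')
#'
#' For each neuron, discriminability of detected (Hit) from non-detected
#' (Miss) stimulus trials based on the trial statistic "mean z over
#' valid stimulation frames":
#' `d' = (mean_det - mean_non) / sqrt(0.5 * (var_det + var_non))`.
#' Requires at least `min_per_class` trials in each class; a zero pooled
#' SD leaves d' undefined (flagged).
#'
#' @param at an `aligned_tensor`.
#' @param min_per_class minimum trials per class (default 2).
#' @return tibble with `neuron`, `celltype`, `d_prime`, `defined`,
#'   `n_detected`, `n_nondetected`. The fraction of detection-encoding
#'   neurons (d' > 1 among defined) is attached as attribute
#'   `encoder_fraction`.
#' @export
neuron_dprime <- function(at, min_per_class = 2) {
  m <- trial_mean_stim_z(at)
  go <- at$meta$trial_type == "go" & at$meta$included
  det <- go & at$meta$detected
  non <- go & !at$meta$detected
  res <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
    a <- m[det, j]; b <- m[non, j]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < min_per_class || length(b) < min_per_class ||
        at$neurons$excluded[j]) {
      return(tibble::tibble(neuron = j, d_prime = NA_real_, defined = FALSE,
                            n_detected = length(a), n_nondetected = length(b)))
    }
    pooled <- sqrt(0.5 * (stats::var(a) + stats::var(b)))
    if (!is.finite(pooled) || pooled == 0) {
      return(tibble::tibble(neuron = j, d_prime = NA_real_, defined = FALSE,
                            n_detected = length(a), n_nondetected = length(b)))
    }
    tibble::tibble(neuron = j, d_prime = (mean(a) - mean(b)) / pooled,
                   defined = TRUE,
                   n_detected = length(a), n_nondetected = length(b))
  })
  res$celltype <- as.character(at$neurons$celltype[res$neuron])
  res <- dplyr::relocate(res, "celltype", .after = "neuron")
  ok <- res$defined
  attr(res, "encoder_fraction") <-
    if (any(ok)) mean(res$d_prime[ok] > 1) else NA_real_
  res
}

#' Fraction of detection-encoding neurons
#'
#' @param dp result of [neuron_dprime()].
#' @param cutoff d' cutoff (neurons above it count as encoders).
#' @return scalar fraction among neurons with defined d'.
#' @export
encoder_fraction <- function(dp, cutoff = 1) {
  ok <- dp$defined
  if (!any(ok)) return(NA_real_)
  mean(dp$d_prime[ok] > cutoff)
}

#' Run the full response-classification stage on one session
#'
#' Convenience wrapper: neuropil-corrects, computes baselines and dF/F,
#' aligns and z-scores, builds per-neuron null distributions and
#' classifies recruitment.
#'
#' @param session a `synthetic_session` (or any list with `trials` and
#'   `traces`).
#' @param seed seed for the null sampling.
#' @param n_null null sample size.
#' @param ... passed on to [classify_recruitment()].
#' @return list with `aligned`, `recruitment`, `nulls`, `dff`.
#' @export
session_responses <- function(session, seed = 1, n_null = 1999, ...) {
  ts <- session$traces
  fc <- neuropil_correct(ts$F, ts$Fneu)
  bl <- baseline_f(fc, ts$frame_rate_hz)
  d <- suppressMessages(dff(fc, bl))
  at <- suppressMessages(align_trials(d, session$trials, ts$frame_rate_hz,
                                      celltype = ts$celltype))
  zfull <- recording_zscores(d, at)
  elig <- eligibility_mask(session$trials, ncol(zfull), ts$frame_rate_hz)
  nulls <- build_nulls(zfull, elig, n = n_null, seed = seed)
  rec <- classify_recruitment(at, nulls, ...)
  list(aligned = at, recruitment = rec, nulls = nulls, dff = d)
}
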