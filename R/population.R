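#' Trinary response vectors
#'
#' Each neuron is represented as a vector over included trials with
#' entries +1 (activated), -1 (inhibited), 0 (non-responsive).
#'
#' @param rec a `recruitment`.
#' @param trials optional logical/integer selection of trials (rows of
#'   the label matrix); defaults to all included trials.
#' @return neurons x trials integer matrix (excluded neurons dropped).
#' @export
trinary_vectors <- function(rec, trials = NULL) {
  rows <- which(rec$meta$included)
  if (!is.null(trials)) {
    rows <- if (is.logical(trials)) which(trials & rec$meta$included)
            else intersect(trials, rows)
  }
  keep <- which(!rec$neurons$excluded)
  t(rec$labels[rows, keep, drop = FALSE])
}

#' Mean pairwise ensemble cosine similarity
#'
#' Cosine similarity between every pair of same-type neurons'
#' trinary response vectors, averaged over the off-diagonal. Neurons
#' whose vector is all zero have no direction and are excluded from the
#' mean (their count is reported).
#'
#' @param rec a `recruitment`, or a plain neurons x trials matrix of
#'   trinary vectors.
#' @param celltype restrict to `"pyr"` or `"inh"`; `NULL` uses all
#'   neurons together.
#' @param trials optional trial selection (see [trinary_vectors()]).
#' @return one-row tibble with `celltype`, `mean_cosine`, `n_neurons`
#'   (entering the mean), `n_pairs`, `n_zero_excluded`.
#' @export
ensemble_cosine <- function(rec, celltype = NULL, trials = NULL) {
  if (inherits(rec, "recruitment")) {
    v <- trinary_vectors(rec, trials)
    ct <- as.character(rec$neurons$celltype[!rec$neurons$excluded])
    if (!is.null(celltype)) v <- v[ct == celltype, , drop = FALSE]
  } else {
    v <- as.matrix(rec)
  }
  v[is.na(v)] <- 0L
  norms <- sqrt(rowSums(v^2))
  zero <- norms == 0
  v <- v[!zero, , drop = FALSE]
  norms <- norms[!zero]
  n <- nrow(v)
  mean_cos <- if (n >= 2) {
    G <- tcrossprod(v) / outer(norms, norms)
    (sum(G) - n) / (n * (n - 1))
  } else {
    NA_real_
  }
  tibble::tibble(celltype = celltype %||% "all",
                 mean_cosine = mean_cos,
                 n_neurons = n,
                 n_pairs = n * (n - 1) / 2,
                 n_zero_excluded = sum(zero))
}

#' Per-trial excitation/inhibition ratio
#'
#' Number of activated pyramidal neurons divided by the number of
#' activated interneurons on each trial. Trials with zero activated
#' interneurons are undefined and excluded from aggregates (their count
#' is reported).
#'
#' @param rec a `recruitment`.
#' @return list with `per_trial` (tibble: `trial_idx`, `trial_type`,
#'   `detected`, `n_act_pyr`, `n_act_inh`, `ei_ratio`, `defined`),
#'   `by_condition` (mean defined ratio for all / detected /
#'   non-detected stimulus trials), `n_undefined`.
#' @export
ei_ratio <- function(rec) {
  pyr <- which(rec$neurons$celltype == "pyr" & !rec$neurons$excluded)
  inh <- which(rec$neurons$celltype == "inh" & !rec$neurons$excluded)
  rows <- which(rec$meta$included)
  per_trial <- tibble::tibble(
    trial_idx = rec$meta$trial_idx[rows],
    trial_type = rec$meta$trial_type[rows],
    detected = rec$meta$detected[rows],
    n_act_pyr = rowSums(rec$labels[rows, pyr, drop = FALSE] == 1, na.rm = TRUE),
    n_act_inh = rowSums(rec$labels[rows, inh, drop = FALSE] == 1, na.rm = TRUE))
  per_trial$defined <- per_trial$n_act_inh > 0
  per_trial$ei_ratio <- ifelse(per_trial$defined,
                               per_trial$n_act_pyr / per_trial$n_act_inh,
                               NA_real_)
  go <- dplyr::filter(per_trial, .data$trial_type == "go", .data$defined)
  by_condition <- dplyr::bind_rows(
    tibble::tibble(condition = "all", mean_ei = mean(go$ei_ratio),
                   n_trials = nrow(go)),
    go |>
      dplyr::group_by(condition = ifelse(.data$detected, "detected",
                                         "non-detected")) |>
      dplyr::summarise(mean_ei = mean(.data$ei_ratio),
                       n_trials = dplyr::n(), .groups = "drop"))
  list(per_trial = per_trial, by_condition = by_condition,
       n_undefined = sum(!per_trial$defined))
}

#' Single-cell signal-to-noise ratio
#'
#' Per neuron, the mean over stimulus trials of the absolute difference
#' between the trial's mean stimulation-window z-score and the neuron's
#' mean activity during catch trials (whose window sits at the scheduled
#' sham stimulus time). Variants over all stimulus trials, detected-only
#' and non-detected-only trial sets are reported.
#'
#' @param at an `aligned_tensor`.
#' @return tibble with `neuron`, `celltype`, `snr_all`, `snr_detected`,
#'   `snr_nondetected`, `n_catch`.
#' @export
single_cell_snr <- function(at) {
  m <- trial_mean_stim_z(at)
  go <- at$meta$trial_type == "go" & at$meta$included
  catch <- at$meta$trial_type == "nogo" & at$meta$included
  assert_that(sum(catch) >= 1, "single-cell SNR needs at least one catch trial")
  det <- go & at$meta$detected
  non <- go & !at$meta$detected
  snr_for <- function(j, rows) {
    x <- m[rows, j]; x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    mean(abs(x - mean(m[catch, j], na.rm = TRUE)))
  }
  purrr::map_dfr(seq_len(ncol(m)), function(j) tibble::tibble(
    neuron = j,
    celltype = as.character(at$neurons$celltype[j]),
    snr_all = if (at$neurons$excluded[j]) NA_real_ else snr_for(j, go),
    snr_detected = if (at$neurons$excluded[j]) NA_real_ else snr_for(j, det),
    snr_nondetected = if (at$neurons$excluded[j]) NA_real_ else snr_for(j, non),
    n_catch = sum(catch)))
}

#' Population signal-to-noise ratio
#'
#' Per stimulus trial, the recruited fraction of the population divided
#' by the mean recruited fraction during catch (No-Go) trials. Also
#' reports the correlated-ensemble ratio: mean pairwise cosine
#' similarity restricted to stimulus trials divided by the same quantity
#' restricted to catch trials.
#'
#' @param rec a `recruitment`.
#' @param add_one add-one smoothing of the catch denominator (off by
#'   default; without it, a zero catch recruitment mean flags the ratio
#'   undefined).
#' @return list with `per_trial` (tibble: `trial_idx`, `detected`,
#'   `frac_recruited`, `pop_snr`), `catch_mean_fraction`, summary
#'   `by_condition` (all / detected / non-detected mean ratios),
#'   `cosine_ratio`, and `defined`.
#' @export
population_snr <- function(rec, add_one = FALSE) {
  keep <- which(!rec$neurons$excluded)
  lab <- rec$labels[, keep, drop = FALSE]
  frac <- rowMeans(lab != 0)
  rows_go <- which(rec$meta$trial_type == "go" & rec$meta$included)
  rows_catch <- which(rec$meta$trial_type == "nogo" & rec$meta$included)
  assert_that(length(rows_catch) >= 1, "population SNR needs catch trials")
  catch_mean <- mean(frac[rows_catch])
  n_neu <- length(keep)
  if (add_one) {
    catch_mean <- (catch_mean * n_neu + 1) / (n_neu + 1)
  }
  defined <- catch_mean > 0
  per_trial <- tibble::tibble(
    trial_idx = rec$meta$trial_idx[rows_go],
    detected = rec$meta$detected[rows_go],
    frac_recruited = frac[rows_go],
    pop_snr = if (defined) frac[rows_go] / catch_mean else NA_real_)
  by_condition <- if (defined) {
    dplyr::bind_rows(
      tibble::tibble(condition = "all", mean_pop_snr = mean(per_trial$pop_snr),
                     n_trials = nrow(per_trial)),
      per_trial |>
        dplyr::group_by(condition = ifelse(.data$detected, "detected",
                                           "non-detected")) |>
        dplyr::summarise(mean_pop_snr = mean(.data$pop_snr),
                         n_trials = dplyr::n(), .groups = "drop"))
  } else {
    tibble::tibble(condition = character(), mean_pop_snr = numeric(),
                   n_trials = integer())
  }
  cos_stim <- ensemble_cosine(rec, trials = rows_go)$mean_cosine
  cos_catch <- ensemble_cosine(rec, trials = rows_catch)$mean_cosine
  cosine_ratio <- if (!is.na(cos_catch) && cos_catch != 0) {
    cos_stim / cos_catch
  } else {
    NA_real_
  }
  list(per_trial = per_trial, catch_mean_fraction = catch_mean,
       by_condition = by_condition, cosine_ratio = cosine_ratio,
       defined = defined)
}

#' Across-animal SNR-recruitment regression
#'
#' Ordinary least-squares regression of per-animal recruited fraction on
#' per-animal single-cell SNR, with the Pearson correlation and its
#' two-sided p-value. The animal is the statistical unit.
#'
#' @param df data frame with one row per animal and columns `snr` and
#'   `recruited_fraction` (extra columns ignored).
#' @return one-row tibble with `slope`, `intercept`, `r`, `p`, `n`,
#'   `defined` (`FALSE` when the predictor has zero variance).
#' @export
snr_recruitment_cor <- function(df) {
  assert_that(all(c("snr", "recruited_fraction") %in% names(df)),
              "df needs columns snr and recruited_fraction")
  d <- dplyr::filter(df, is.finite(.data$snr),
                     is.finite(.data$recruited_fraction))
  assert_that(nrow(d) >= 3, "need at least 3 animals")
  if (stats::sd(d$snr) == 0) {
    return(tibble::tibble(slope = NA_real_, intercept = NA_real_,
                          r = NA_real_, p = NA_real_, n = nrow(d),
                          defined = FALSE))
  }
  fit <- stats::lm(recruited_fraction ~ snr, data = d)
  ct <- suppressWarnings(stats::cor.test(d$snr, d$recruited_fraction))
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = unname(ct$estimate), p = ct$p.value,
                 n = nrow(d), defined = TRUE)
}
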