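#' Behavioral outcome rates of a session
#'
#' Computes the four Go/No-Go outcome rates from a trial table. Go trials
#' canceled by pre-stimulus licking (timeouts) received no stimulus and
#' are excluded from the Go denominator; the pre-stimulus lick rate is
#' reported as timeouts divided by all scheduled Go trials.
#'
#' @param trials a trial table (see [simulate_trials()] for the schema);
#'   the `outcome` column must be filled for non-timeout trials.
#' @return a one-row tibble with `n_go`, `n_nogo`, `hit_rate`,
#'   `miss_rate`, `cr_rate`, `fa_rate`, `prestim_lick_rate`, and logical
#'   flags `go_defined` / `nogo_defined` that are `FALSE` (with `NA`
#'   rates) when a denominator is zero.
#' @examples
#' tr <- simulate_behavior(simulate_trials(sim_config(), 1), wt_mouse(),
#'                         sim_config(), 1)
#' outcome_rates(tr)
#' @export
outcome_rates <- function(trials) {
  is_go_all <- trials$trial_type == "go"
  go <- trials[is_go_all & !trials$timeout, ]
  nogo <- trials[!is_go_all, ]
  n_go <- nrow(go); n_nogo <- nrow(nogo)
  go_defined <- n_go > 0; nogo_defined <- n_nogo > 0
  tibble::tibble(
    n_go = n_go,
    n_nogo = n_nogo,
    hit_rate = if (go_defined) mean(go$outcome == "hit") else NA_real_,
    miss_rate = if (go_defined) mean(go$outcome == "miss") else NA_real_,
    cr_rate = if (nogo_defined) mean(nogo$outcome == "cr") else NA_real_,
    fa_rate = if (nogo_defined) mean(nogo$outcome == "fa") else NA_real_,
    prestim_lick_rate = if (sum(is_go_all) > 0) {
      sum(trials$timeout[is_go_all]) / sum(is_go_all)
    } else NA_real_,
    go_defined = go_defined,
    nogo_defined = nogo_defined
  )
}

#' Per-amplitude hit rates
#'
#' @param trials a trial table with behavior.
#' @return tibble with `amplitude_um`, `n`, `hits`, `hit_rate` over
#'   non-timeout Go trials.
#' @export
amplitude_hit_rates <- function(trials) {
  trials |>
    dplyr::filter(.data$trial_type == "go", !.data$timeout) |>
    dplyr::group_by(amplitude_um = .data$amplitude_um) |>
    dplyr::summarise(n = dplyr::n(),
                     hits = sum(.data$outcome == "hit"),
                     hit_rate = .data$hits / .data$n,
                     .groups = "drop") |>
    dplyr::arrange(.data$amplitude_um)
}

#' Fit a psychometric curve to Go-trial detection
#'
#' Fits detection probability against stimulus amplitude with a
#' binomial GLM (logit link), the standard sigmoid psychometric model.
#' The detection threshold is the amplitude at which the fitted curve
#' crosses P = 0.5 (the sigmoid inflection point for the logistic), and
#' perceptual accuracy is summarized as the maximum derivative of the
#' fitted curve (`slope / 4` on the probability scale).
#'
#' When the fit separates perfectly (divergent slope), the model is refit
#' with a small L2 ridge penalty on the coefficients and flagged in the
#' diagnostics. A threshold outside the tested amplitude range, or a
#' non-positive slope, is flagged undefined rather than reported
#' silently.
#'
#' @param trials either a trial table or a per-amplitude summary from
#'   [amplitude_hit_rates()].
#' @param ridge_lambda penalty used by the separation fallback.
#' @return an object of class `psychometric_fit` with elements
#'   `threshold_um`, `slope` (logit scale, per µm), `intercept`,
#'   `accuracy_slope`, `rates` (per-amplitude tibble), and `flags`.
#'   Methods: [tidy()][generics::tidy], [glance()][generics::glance],
#'   [autoplot()][ggplot2::autoplot].
#' @export
fit_psychometric <- function(trials, ridge_lambda = 1e-3) {
  rates <- if (all(c("hits", "n") %in% names(trials))) {
    trials
  } else {
    amplitude_hit_rates(trials)
  }
  rates <- dplyr::filter(rates, .data$n > 0, !is.na(.data$amplitude_um))
  assert_that(nrow(rates) >= 2,
              "need Go trials at >= 2 distinct amplitudes to fit")

  flags <- list(separation = FALSE, threshold_defined = TRUE,
                degenerate = FALSE)

  all_zero <- all(rates$hits == 0)
  all_one <- all(rates$hits == rates$n)
  if (all_zero || all_one) {
    flags$threshold_defined <- FALSE
    flags$degenerate <- TRUE
    coefs <- c(`(Intercept)` = if (all_one) Inf else -Inf, amplitude_um = 0)
    fit <- NULL
  } else {
    saw_separation <- FALSE
    fit <- withCallingHandlers(
      stats::glm(cbind(hits, n - hits) ~ amplitude_um,
                 family = stats::binomial(), data = rates),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge",
                  conditionMessage(w))) {
          saw_separation <<- TRUE
        }
        invokeRestart("muffleWarning")
      })
    coefs <- stats::coef(fit)
    separated <- saw_separation || !fit$converged ||
      abs(coefs[["amplitude_um"]]) > 15
    if (separated) {
      flags$separation <- TRUE
      # ridge fallback on expanded Bernoulli responses
      y <- c(rep(1, sum(rates$hits)), rep(0, sum(rates$n - rates$hits)))
      x <- c(rep(rates$amplitude_um, rates$hits),
             rep(rates$amplitude_um, rates$n - rates$hits))
      rf <- glmnet::glmnet(cbind(amp = x, aux = 0), y, family = "binomial",
                           alpha = 0, lambda = ridge_lambda,
                           standardize = FALSE)
      b <- as.numeric(stats::coef(rf))
      coefs <- c(`(Intercept)` = b[1], amplitude_um = b[2])
    }
  }

  slope <- unname(coefs[["amplitude_um"]])
  intercept <- unname(coefs[["(Intercept)"]])
  threshold <- if (is.finite(slope) && slope > 0) -intercept / slope else NA_real_
  if (!is.na(threshold) &&
      (threshold < min(rates$amplitude_um) - diff(range(rates$amplitude_um)) ||
       threshold > max(rates$amplitude_um) + diff(range(rates$amplitude_um)))) {
    flags$threshold_defined <- FALSE
  }
  if (is.na(threshold)) flags$threshold_defined <- FALSE

  structure(list(
    threshold_um = if (flags$threshold_defined) threshold else NA_real_,
    slope = slope,
    intercept = intercept,
    accuracy_slope = if (is.finite(slope)) slope / 4 else NA_real_,
    rates = rates,
    fit = fit,
    flags = flags
  ), class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> threshold %.2f um, slope %.3f /um (accuracy %.3f)\n",
              x$threshold_um, x$slope, x$accuracy_slope))
  if (x$flags$separation) cat("  note: perfect separation; ridge fallback used\n")
  if (!x$flags$threshold_defined) cat("  note: threshold undefined\n")
  invisible(x)
}

#' Predict detection probability from a psychometric fit
#' @param object a `psychometric_fit`.
#' @param amplitude_um amplitudes at which to evaluate the curve.
#' @param ... unused.
#' @return numeric vector of fitted detection probabilities.
#' @export
predict.psychometric_fit <- function(object, amplitude_um, ...) {
  stats::plogis(object$intercept + object$slope * amplitude_um)
}

#' Relative criterion c' from hit and false-alarm rates
#'
#' Signal-detection-theory response-bias measure
#' `c' = -((z(Hit) + z(FA)) / 2) / (z(Hit) - z(FA))`, where `z` is the
#' standard-normal quantile. Rates of exactly 0 or 1 are clipped to
#' `1/(2n)` and `1 - 1/(2n)` of their trial counts before the quantile
#' transform (the standard log-linear correction). `c'` is undefined when
#' the clipped rates coincide (`z(Hit) = z(FA)`).
#'
#' @param hit_rate,fa_rate observed rates in \[0, 1\].
#' @param n_go,n_nogo trial counts behind each rate (used for clipping).
#' @return one-row tibble with `c_prime`, `z_hit`, `z_fa`, `defined`.
#' @examples
#' criterion_c(0.8, 0.2, 100, 30) # balanced rates: c' = 0
#' @export
criterion_c <- function(hit_rate, fa_rate, n_go, n_nogo) {
  assert_that(hit_rate >= 0 && hit_rate <= 1 && fa_rate >= 0 && fa_rate <= 1,
              "rates must lie in [0, 1]")
  h <- clamp(hit_rate, 1 / (2 * n_go), 1 - 1 / (2 * n_go))
  f <- clamp(fa_rate, 1 / (2 * n_nogo), 1 - 1 / (2 * n_nogo))
  z_hit <- stats::qnorm(h)
  z_fa <- stats::qnorm(f)
  defined <- abs(z_hit - z_fa) > .Machine$double.eps^0.5
  tibble::tibble(
    c_prime = if (defined) -0.5 * (z_hit + z_fa) / (z_hit - z_fa) else NA_real_,
    z_hit = z_hit, z_fa = z_fa, defined = defined)
}

#' Trial-by-trial variability of detection
#'
#' Variance of the Hit indicator across Go trials at each amplitude
#' (`mean((x - mean(x))^2)`, the Bernoulli variance `p(1-p)`, bounded by
#' 0.25). When a detection threshold is supplied, the profile is also
#' summarized as a normalized triplet at the sub-threshold
#' (threshold - 2 µm), threshold, and supra-threshold (threshold + 2 µm)
#' amplitudes, using the nearest delivered amplitude for each and
#' normalizing by the Bernoulli maximum 0.25.
#'
#' @param trials trial table with behavior.
#' @param threshold_um the mouse's detection threshold, or `NULL` to skip
#'   the triplet.
#' @return a list with `per_amplitude` (tibble: `amplitude_um`, `n`,
#'   `variance`, `low_n` flag for n < 2), `mean_variance`, and `triplet`
#'   (tibble with `position`, `target_um`, `amplitude_um`, `variance`,
#'   `normalized`; `NULL` when no threshold given).
#' @export
trial_variability <- function(trials, threshold_um = NULL) {
  go <- dplyr::filter(trials, .data$trial_type == "go", !.data$timeout)
  per_amp <- go |>
    dplyr::group_by(amplitude_um = .data$amplitude_um) |>
    dplyr::summarise(
      n = dplyr::n(),
      variance = mean((as.numeric(.data$outcome == "hit") -
                         mean(.data$outcome == "hit"))^2),
      .groups = "drop") |>
    dplyr::mutate(low_n = .data$n < 2) |>
    dplyr::arrange(.data$amplitude_um)

  triplet <- NULL
  if (!is.null(threshold_um) && !is.na(threshold_um)) {
    targets <- tibble::tibble(
      position = c("subthreshold", "threshold", "suprathreshold"),
      target_um = threshold_um + c(-2, 0, 2))
    triplet <- targets |>
      dplyr::rowwise() |>
      dplyr::mutate(
        amplitude_um = per_amp$amplitude_um[
          which.min(abs(per_amp$amplitude_um - .data$target_um))],
        variance = per_amp$variance[per_amp$amplitude_um == .data$amplitude_um],
        normalized = .data$variance / 0.25) |>
      dplyr::ungroup()
  }
  list(per_amplitude = per_amp,
       mean_variance = mean(per_amp$variance),
       triplet = triplet)
}

#' Cluster mice into detection subgroups
#'
#' k-means (k = 2, multiple restarts, seeded) on the per-mouse hit-rate
#' profile across stimulus amplitudes. The cluster with the lower mean
#' hit rate is labeled `"hyposensitive-like"`, the other `"typical"`.
#' Missing amplitudes are imputed by the within-mouse mean and flagged.
#'
#' @param hit_matrix data frame with a `mouse_id` column and one numeric
#'   column per amplitude (mice x amplitudes), or a plain numeric matrix
#'   with rownames as mouse ids.
#' @param seed seed for the k-means restarts.
#' @param nstart number of random restarts.
#' @return tibble with `mouse_id`, `cluster` (1/2), `subgroup`
#'   (`"typical"`/`"hyposensitive-like"`), plus attributes `imputed`
#'   (count of imputed cells) and `degenerate` (TRUE when all profiles
#'   coincide and only one cluster exists).
#' @export
cluster_subgroups <- function(hit_matrix, seed = 1, nstart = 10) {
  if (is.data.frame(hit_matrix)) {
    assert_that("mouse_id" %in% names(hit_matrix),
                "hit_matrix data frame needs a mouse_id column")
    ids <- as.character(hit_matrix$mouse_id)
    m <- as.matrix(hit_matrix[setdiff(names(hit_matrix), "mouse_id")])
  } else {
    m <- as.matrix(hit_matrix)
    ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  }
  assert_that(nrow(m) >= 2, "need at least 2 mice to cluster")

  imputed <- 0L
  if (anyNA(m)) {
    for (i in seq_len(nrow(m))) {
      miss <- is.na(m[i, ])
      if (any(miss)) {
        m[i, miss] <- mean(m[i, !miss])
        imputed <- imputed + sum(miss)
      }
    }
  }

  if (nrow(unique(m)) < 2) {
    out <- tibble::tibble(mouse_id = ids, cluster = 1L,
                          subgroup = "typical")
    attr(out, "degenerate") <- TRUE
    attr(out, "imputed") <- imputed
    return(out)
  }

  km <- with_rng_seed(seed, stats::kmeans(m, centers = 2, nstart = nstart))
  lower <- which.min(rowMeans(km$centers))
  out <- tibble::tibble(
    mouse_id = ids,
    cluster = unname(as.integer(km$cluster)),
    subgroup = unname(ifelse(km$cluster == lower, "hyposensitive-like",
                             "typical")))
  attr(out, "degenerate") <- FALSE
  attr(out, "imputed") <- imputed
  out
}

#' Session inclusion check
#'
#' A testing session is included only when strictly fewer than 40% of its
#' No-Go trials were unsuccessful (false alarms).
#'
#' @param trials trial table with behavior.
#' @param max_fa_rate exclusion boundary (strict inequality).
#' @return one-row tibble with `fa_rate` and logical `include`.
#' @export
session_qc <- function(trials, max_fa_rate = 0.40) {
  r <- outcome_rates(trials)
  tibble::tibble(fa_rate = r$fa_rate,
                 include = !is.na(r$fa_rate) & r$fa_rate < max_fa_rate)
}

#' Learning-criterion check over daily performance
#'
#' Applies the phase criterion to 3-day rolling means of daily rates:
#' training requires a rolling Hit rate at or above `hit_criterion`
#' (default 80%; a 70% variant is available via the argument) together
#' with a rolling false-alarm rate below 30%; pre-training requires the
#' Hit criterion with spontaneous licking below 40%.
#'
#' @param daily_rates tibble with columns `day`, `hit_rate`, `fa_rate`
#'   (for pre-training, `fa_rate` holds the spontaneous-licking rate).
#' @param phase `"training"` or `"pretraining"`.
#' @param hit_criterion rolling Hit-rate requirement.
#' @return a list with `daily` (tibble adding `roll_hit`, `roll_fa`,
#'   `pass` for each day from day 3 on), `first_pass_day` (`NA` if never
#'   passed), and `sufficient` (`FALSE`, with empty results, when fewer
#'   than 3 days are supplied).
#' @export
learning_criterion <- function(daily_rates,
                               phase = c("training", "pretraining"),
                               hit_criterion = 0.80) {
  phase <- match.arg(phase)
  fa_criterion <- if (phase == "training") 0.30 else 0.40
  d <- dplyr::arrange(daily_rates, .data$day)
  if (nrow(d) < 3) {
    return(list(daily = tibble::tibble(), first_pass_day = NA_integer_,
                sufficient = FALSE))
  }
  roll <- function(x) stats::filter(x, rep(1 / 3, 3), sides = 1)
  d$roll_hit <- as.numeric(roll(d$hit_rate))
  d$roll_fa <- as.numeric(roll(d$fa_rate))
  d$pass <- !is.na(d$roll_hit) & d$roll_hit >= hit_criterion &
    d$roll_fa < fa_criterion
  first <- if (any(d$pass)) d$day[which(d$pass)[1]] else NA_integer_
  list(daily = tibble::as_tibble(d), first_pass_day = first,
       sufficient = TRUE)
}
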