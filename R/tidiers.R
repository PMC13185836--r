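#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a psychometric fit
#'
#' @param x a `psychometric_fit`.
#' @param ... unused.
#' @return tibble of per-amplitude observed and fitted hit rates.
#' @method tidy psychometric_fit
#' @export
tidy.psychometric_fit <- function(x, ...) {
  dplyr::mutate(x$rates, fitted = predict(x, .data$amplitude_um))
}

#' One-row summary of a psychometric fit
#'
#' @param x a `psychometric_fit`.
#' @param ... unused.
#' @return tibble with threshold, slope, accuracy and flags.
#' @method glance psychometric_fit
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(threshold_um = x$threshold_um, slope = x$slope,
                 intercept = x$intercept, accuracy_slope = x$accuracy_slope,
                 threshold_defined = x$flags$threshold_defined,
                 separation = x$flags$separation)
}

#' Tidy per-frame decoding curves
#'
#' @param x a `decoding_result`.
#' @param ... unused.
#' @return long tibble with `time_ms`, `curve`
#'   (hit_accuracy/miss_error x true/shuffled) and `value`.
#' @method tidy decoding_result
#' @export
tidy.decoding_result <- function(x, ...) {
  x$frames |>
    tidyr::pivot_longer(cols = c("hit_accuracy", "miss_error",
                                 "shuffled_hit_accuracy",
                                 "shuffled_miss_error"),
                        names_to = "curve", values_to = "value") |>
    dplyr::select("frame", "rel_frame", "time_ms", "curve", "value")
}

#' One-row decoding summary
#'
#' @param x a `decoding_result`.
#' @param ... unused.
#' @return tibble with stimulation- and pre-stimulus-window accuracies
#'   (true and shuffled) where those frames were decoded.
#' @method glance decoding_result
#' @export
glance.decoding_result <- function(x, ...) {
  safe <- function(...) tryCatch(window_accuracy(x, ...),
                                 error = function(e) NA_real_)
  tibble::tibble(
    n_trials = x$n_trials,
    stim_accuracy = safe("stimulation"),
    stim_shuffled = safe("stimulation", shuffled = TRUE),
    prestim_accuracy = safe("prestim"),
    prestim_shuffled = safe("prestim", shuffled = TRUE))
}

#' Tidy recruitment labels
#'
#' @param x a `recruitment`.
#' @param ... unused.
#' @return long tibble with one row per neuron-trial label.
#' @method tidy recruitment
#' @export
tidy.recruitment <- function(x, ...) {
  lab <- x$labels
  tibble::tibble(
    trial_idx = rep(x$meta$trial_idx, times = ncol(lab)),
    trial_type = rep(x$meta$trial_type, times = ncol(lab)),
    amplitude_um = rep(x$meta$amplitude_um, times = ncol(lab)),
    detected = rep(x$meta$detected, times = ncol(lab)),
    neuron = rep(seq_len(ncol(lab)), each = nrow(lab)),
    celltype = rep(as.character(x$neurons$celltype), each = nrow(lab)),
    label = as.integer(lab)) |>
    dplyr::filter(!is.na(.data$label))
}
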