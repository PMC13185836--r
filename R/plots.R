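#' Plot a psychometric fit
#'
#' Observed per-amplitude hit rates with the fitted logistic curve and
#' the 50% detection-threshold marker.
#'
#' @param object a `psychometric_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot psychometric_fit
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  rng <- range(object$rates$amplitude_um)
  curve <- tibble::tibble(
    amplitude_um = seq(rng[1], rng[2], length.out = 200))
  curve$p <- predict(object, curve$amplitude_um)
  p <- ggplot2::ggplot(object$rates,
                       ggplot2::aes(x = .data$amplitude_um, y = .data$hit_rate)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$p),
                       color = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Stimulus amplitude (µm)", y = "Hit rate") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (!is.na(object$threshold_um)) {
    p <- p + ggplot2::geom_vline(xintercept = object$threshold_um,
                                 linetype = "dashed", color = "grey40")
  }
  p
}

#' Plot frame-by-frame decoding curves
#'
#' Hit-accuracy and Miss-error curves over the aligned window, with the
#' shuffled-label chance curves dashed and the stimulation period
#' shaded.
#'
#' @param object a `decoding_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot decoding_result
#' @export
autoplot.decoding_result <- function(object, ...) {
  d <- tidy(object)
  d$shuffled <- grepl("^shuffled", d$curve)
  d$measure <- sub("^shuffled_", "", d$curve)
  stim_end <- object$window$stim * 1000 / object$window$frame_rate_hz
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms, y = .data$value,
                                  color = .data$measure,
                                  linetype = .data$shuffled)) +
    ggplot2::annotate("rect", xmin = 0, xmax = stim_end, ymin = -Inf,
                      ymax = Inf, alpha = 0.08) +
    ggplot2::geom_hline(yintercept = 0.5, color = "grey70") +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dashed"),
                                   labels = c("true", "shuffled"),
                                   name = NULL) +
    ggplot2::labs(x = "Time from stimulus onset (ms)", y = "Rate",
                  color = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot recruitment versus stimulus amplitude
#'
#' Condition-mean recruited fractions by amplitude, split by cell type
#' and detection.
#'
#' @param rec a `recruitment`.
#' @return a ggplot.
#' @export
plot_recruitment <- function(rec) {
  d <- recruitment_proportions(rec)$by_condition |>
    dplyr::filter(.data$trial_type == "go")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$amplitude_um,
                                  y = .data$frac_recruited,
                                  color = .data$celltype,
                                  linetype = .data$detected)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Stimulus amplitude (µm)",
                  y = "Recruited fraction", color = "Cell type",
                  linetype = "Detected") +
    ggplot2::theme_minimal()
}
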