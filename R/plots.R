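#' Plot a prediction ensemble
#'
#' Dot plot of the per-method CID predictions with the ensemble mean as a
#' horizontal line, the usual way the method-dependence of a chiroptical
#' prediction is displayed.
#'
#' @param object A `prediction_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prediction_ensemble <- function(object, ...) {
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method_label, y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_hline(yintercept = object$summary$delta_mean,
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = NULL, y = expression(Delta),
      title = sprintf("CID predictions at %g nm (%s)",
                      object$summary$wavelength_nm, object$summary$geometry),
      subtitle = sprintf("ensemble mean %.3g (dashed)",
                         object$summary$delta_mean)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot simulated SCP measurement replicates
#'
#' Histogram of the raw CID over replicates with the replicate mean marked;
#' the spread visualizes the shot-noise limit at the accumulated counts.
#'
#' @param object An `scp_measurement` with at least one replicate.
#' @param true_delta Optional true CID to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scp_measurement <- function(object, true_delta = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$delta_raw)) +
    ggplot2::geom_histogram(bins = max(10, min(40, nrow(object) %/% 5)),
                            fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = mean(object$delta_raw),
                        colour = "steelblue", linetype = "dashed") +
    ggplot2::labs(x = expression(Delta[raw]), y = "replicates",
                  title = "Simulated SCP measurements") +
    ggplot2::theme_minimal()
  if (!is.null(true_delta)) {
    p <- p + ggplot2::geom_vline(xintercept = true_delta, colour = "firebrick")
  }
  p
}
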