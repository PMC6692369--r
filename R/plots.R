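#' Bar chart of called event-type proportions
#'
#' @param summary Summary tibble from [summarize_events()] (or a
#'   `splice_pipeline` object).
#' @return A ggplot object.
#' @export
plot_event_summary <- function(summary) {
  if (inherits(summary, "splice_pipeline")) {
    summary <- summary$summary
  }
  df <- summary[summary$section == "event_type", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$prop)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "event type", y = "proportion of called events") +
    ggplot2::theme_minimal()
}

#' PSI scatter of the two conditions
#'
#' Each point is a junction; called junctions are highlighted.  Points far
#' from the diagonal have large |dPSI|.
#'
#' @param calls Calls tibble from [call_differential()].
#' @return A ggplot object.
#' @export
plot_psi <- function(calls) {
  df <- calls[!is.na(calls$dpsi), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$psi_A, y = .data$psi_B,
                                   colour = .data$differential)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "PSI (condition A)", y = "PSI (condition B)",
                  colour = "differential") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.bs_distance_test <- function(object, ...) {
  ggplot2::ggplot(object$distances,
                  ggplot2::aes(x = .data$distance, colour = .data$group)) +
    ggplot2::stat_ecdf(linewidth = 0.8) +
    ggplot2::labs(x = "5'SS-BS distance (nt)", y = "ECDF",
                  subtitle = sprintf("KS D = %.3f, p = %.3g",
                                     object$ks$statistic, object$ks$p_value)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.splice_pipeline <- function(object, ...) {
  plot_event_summary(object)
}
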