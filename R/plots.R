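#' Plot the per-iteration classification performance distributions
#'
#' Box plot of the overall accuracy and multi-class MCC across the
#' repeated cross-validation iterations of an [profile_errors()] run —
#' the stability view of the classifier under reshuffled folds and
#' jittered C.
#'
#' @param object An `error_profiles` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.error_profiles <- function(object, ...) {
  im <- tidyr::pivot_longer(object$iteration_metrics,
                            cols = c("accuracy", "mcc"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(im, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(width = 0.4, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "value",
                  title = sprintf("Performance over %d repeated CV iterations",
                                  nrow(object$iteration_metrics))) +
    ggplot2::theme_minimal()
}

#' Plot a label-noise detection report
#'
#' Error rate against voting ratio for every frequently misclassified
#' sequence, colored by error magnitude; sequences above the CDV
#' threshold are shaped differently. Gives a one-look summary of which
#' sequences the detector shortlists and why.
#'
#' @param object A `noise_report` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.noise_report <- function(object, ...) {
  d <- object$frequent
  if (nrow(d) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No frequently misclassified sequences") +
             ggplot2::theme_minimal())
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$R, y = .data$ER,
                                  color = .data$magnitude,
                                  shape = .data$large_CDV)) +
    ggplot2::geom_point(size = 2.5, alpha = 0.9) +
    ggplot2::geom_vline(xintercept = object$config$theta_R,
                        linetype = "dashed", color = "grey50") +
    ggplot2::scale_color_manual(values = c(large = "#c0392b",
                                           small = "#2980b9")) +
    ggplot2::labs(x = "voting ratio R (true / most-predicted class votes)",
                  y = "error rate ER (%)",
                  color = "error magnitude", shape = "|CDV| large") +
    ggplot2::theme_minimal()
}
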