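# ggplot2 visualizations of fitted models and classification results.

#' Diagnostic plot of a fitted gamma null model
#'
#' Quantile-quantile plot of the ratio residuals `r_cf / mu` against the
#' fitted gamma law (shape `alpha`, mean 1): calibration on the null
#' triplets is a straight unit line.
#'
#' @param object A `gamma_null` model.
#' @param triplets The triplets the model was fitted to (or fresh null
#'   triplets).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gamma_null <- function(object, triplets, ...) {
  d <- triplets$r_cf / predict_null_mean(object, triplets)
  n <- length(d)
  df <- tibble(
    theoretical = qgamma(ppoints(n), shape = object$shape,
                         scale = 1 / object$shape),
    observed = sort(d)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$theoretical, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::labs(
      x = "theoretical gamma quantile",
      y = "observed r_cf / fitted mean",
      title = sprintf("Gamma null calibration (shape = %.2f, n = %d)",
                      object$shape, n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-variant significance coloured by class
#'
#' Log2 combined p-values along the protein with the classification cutoffs
#' drawn as horizontal lines.
#'
#' @param results Tibble from [classify_variants()].
#' @param thresholds The [classification_thresholds()] used.
#' @return A ggplot.
#' @export
plot_classification <- function(results,
                                thresholds = classification_thresholds()) {
  check_columns(results, c("residue_index", "log2_p", "class"))
  df <- mutate(results, log2_p = pmax(.data$log2_p, -400))
  ggplot2::ggplot(df, ggplot2::aes(.data$residue_index, .data$log2_p,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = thresholds$log2p_deleterious,
                        linetype = 2) +
    ggplot2::geom_hline(yintercept = thresholds$log2p_neutral,
                        linetype = 3) +
    ggplot2::scale_colour_manual(values = c(deleterious = "#b2182b",
                                            indeterminate = "grey55",
                                            neutral = "#2166ac"),
                                 drop = FALSE) +
    ggplot2::labs(x = "residue", y = "log2 combined p-value",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot the per-residue deleterious fraction with domain shading
#'
#' @param summary Output of [residue_summary()].
#' @param domains Domain map for shading (see [ankyrin_domains()]).
#' @return A ggplot.
#' @export
plot_residue_landscape <- function(summary, domains = ankyrin_domains()) {
  per <- summary$residues
  ggplot2::ggplot(per) +
    ggplot2::geom_rect(
      data = domains,
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                   ymin = -Inf, ymax = Inf),
      fill = "grey85", alpha = 0.6, inherit.aes = FALSE) +
    ggplot2::geom_col(ggplot2::aes(.data$residue_index, .data$fraction),
                      width = 0.9, fill = "#b2182b") +
    ggplot2::geom_hline(yintercept = summary$overall$mean, linetype = 2) +
    ggplot2::labs(x = "residue",
                  y = "fraction of missense variants deleterious") +
    ggplot2::theme_minimal()
}
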