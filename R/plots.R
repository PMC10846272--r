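# ggplot2 autoplot() methods for the main result types.

#' Plot NMDS sample scores
#'
#' @param object An `nmds_ord` from [nmds()].
#' @param groups Optional group label per sample for colouring.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nmds_ord
#' @export
autoplot.nmds_ord <- function(object, groups = NULL, ...) {
  df <- object$scores
  if (!is.null(groups)) df$group <- groups
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2)) +
    ggplot2::labs(
      subtitle = sprintf("stress-1 = %.3f", object$stress),
      x = "NMDS1", y = "NMDS2") +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  }
}

#' Plot assembly-process fractions
#'
#' @param object An `assembly_result` from [classify_processes()].
#' @param ... Unused.
#' @return A ggplot bar chart of process fractions.
#' @method autoplot assembly_result
#' @export
autoplot.assembly_result <- function(object, ...) {
  f <- object$fractions
  f$process <- factor(f$process, levels = rev(f$process))
  ggplot2::ggplot(f, ggplot2::aes(x = .data$fraction, y = .data$process)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%",
                                                             100 * v)) +
    ggplot2::labs(x = "Fraction of classified pairs", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot betaNTI values per pair
#'
#' @param object A `bnti_result` from [beta_nti()].
#' @param ... Unused.
#' @return A ggplot histogram with the +/-2 selection thresholds marked.
#' @method autoplot bnti_result
#' @export
autoplot.bnti_result <- function(object, ...) {
  df <- tidy.bnti_result(object)
  df <- df[!df$degenerate, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bnti)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60") +
    ggplot2::geom_vline(xintercept = c(-2, 2), linetype = "dashed") +
    ggplot2::labs(x = "betaNTI", y = "Sample pairs") +
    ggplot2::theme_minimal()
}

#' Plot rarefaction curves
#'
#' @param object A `rarefaction_curve` tibble from [rarefaction_curve()].
#' @param ... Unused.
#' @return A ggplot of mean richness against depth, one line per sample.
#' @method autoplot rarefaction_curve
#' @export
autoplot.rarefaction_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth,
                                       y = .data$mean_richness,
                                       group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "Reads subsampled", y = "Observed OTU richness") +
    ggplot2::theme_minimal()
}

#' Plot distance-decay of similarity
#'
#' @param object A `distance_decay` from [distance_decay()].
#' @param ... Unused.
#' @return A ggplot scatter of similarity against distance with a linear
#'   trend.
#' @method autoplot distance_decay
#' @export
autoplot.distance_decay <- function(object, ...) {
  ggplot2::ggplot(object$scatter,
                  ggplot2::aes(x = .data$distance_km,
                               y = .data$similarity)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "Geographic distance (km)", y = "Bray-Curtis similarity",
      subtitle = sprintf("Mantel rho = %.3f, P = %.3g", object$mantel$r,
                         object$mantel$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot variation-partitioning fractions
#'
#' @param object A `varpart_result` from [varpart3()].
#' @param ... Unused.
#' @return A ggplot bar chart of adjusted R-squared fractions.
#' @method autoplot varpart_result
#' @export
autoplot.varpart_result <- function(object, ...) {
  f <- object$fractions
  f$fraction <- factor(f$fraction, levels = rev(f$fraction))
  ggplot2::ggplot(f, ggplot2::aes(x = .data$adj_r_squared,
                                  y = .data$fraction)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::labs(x = "Adjusted R-squared", y = NULL) +
    ggplot2::theme_minimal()
}
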