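# ggplot2 autoplot methods for the main result types.

#' Plot a LOD profile
#'
#' LOD against map position, one panel per linkage group, with an optional
#' horizontal line at the permutation threshold.
#'
#' @param object A `qtl_scan`.
#' @param threshold Optional genome-wide LOD threshold to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qtl_scan <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object$profile,
    ggplot2::aes(x = .data$pos_cm, y = .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~group, scales = "free_x") +
    ggplot2::labs(x = "Map position (cM)", y = "LOD") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
      linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a genetic map
#'
#' Genetic (cM) against physical (Mb) position per linkage group, the
#' standard collinearity view.
#'
#' @param object A `genetic_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genetic_map <- function(object, ...) {
  ggplot2::ggplot(object$table,
    ggplot2::aes(x = .data$pos / 1e6, y = .data$cm)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~group, scales = "free") +
    ggplot2::labs(x = "Physical position (Mb)", y = "Genetic position (cM)") +
    ggplot2::theme_minimal()
}

#' Plot FCS model fit
#'
#' Observed grades against fitted scores on the training data.
#'
#' @param object An `fcs_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fcs_model <- function(object, ...) {
  df <- tibble::tibble(
    fitted = stats::fitted(object$fit),
    observed = object$fit$model$grade
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Fitted FCS", y = "Observed grade") +
    ggplot2::theme_minimal()
}
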