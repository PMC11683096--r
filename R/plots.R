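#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_point
#'   geom_vline labs theme_minimal annotate geom_raster scale_fill_gradient
#'   coord_equal geom_errorbar geom_col
#' @export
ggplot2::autoplot

#' Plot the empirical ROC curve
#'
#' @param object a `roc_result`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  d <- object$thresholds[order(object$thresholds$sensitivity), ]
  ggplot(d, aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_line(colour = "#2166ac") +
    annotate("point",
             x = 1 - object$specificity, y = object$sensitivity,
             colour = "#b2182b", size = 2) +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("AUC = %.3f (cutoff %.3g)", object$auc,
                         object$cutoff)) +
    theme_minimal()
}

#' Plot mediation path estimates with the indirect-effect CI
#'
#' @param object a `mediation_result`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mediation_result <- function(object, ...) {
  d <- object$paths
  ggplot(d, aes(x = .data$term, y = .data$estimate)) +
    geom_col(fill = "#67a9cf", width = 0.6) +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                  width = 0.2, na.rm = TRUE) +
    labs(x = NULL, y = "Estimate",
         title = sprintf("%s → %s → %s: indirect = %.3f [%.3f, %.3f]",
                         object$x, object$m, object$y, object$indirect,
                         object$ci_low, object$ci_high)) +
    theme_minimal()
}

#' Plot an axial FA (or colour-channel) slice
#'
#' @param field a `tensor_field` or `color_fa` object.
#' @param slice axial slice index (default: middle slice).
#' @param channel for `color_fa`: "red", "green" or "blue".
#' @return A ggplot raster of the slice.
#' @export
plot_fa_slice <- function(field, slice = NULL, channel = "blue") {
  map <- if (inherits(field, "tensor_field")) field$fa else field[[channel]]
  if (is.null(slice)) slice <- ceiling(dim(map)[3] / 2)
  m <- map[, , slice]
  d <- expand.grid(x = seq_len(nrow(m)), y = seq_len(ncol(m)))
  d$value <- as.vector(m)
  ggplot(d, aes(.data$x, .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", na.value = "grey20",
                        limits = c(0, 1)) +
    coord_equal() +
    labs(title = sprintf("axial slice %d", slice), fill = "value") +
    theme_minimal()
}

#' Plot ALPS index by group
#'
#' @param data a data frame with `group` and an ALPS column.
#' @param alps ALPS column name.
#' @return A ggplot.
#' @export
plot_alps_by_group <- function(data, alps = "alps") {
  ggplot(data, aes(x = .data$group, y = .data[[alps]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "#d1e5f0") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    labs(x = NULL, y = "ALPS index") +
    theme_minimal()
}
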