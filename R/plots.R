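# ggplot2 displays for maps, ROC curves, importances and reports.

#' Plot a parameter-map slice
#'
#' @param object A [parameter_map()].
#' @param slice Axial slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot raster of the slice in physical coordinates.
#' @exportS3Method autoplot parameter_map
autoplot.parameter_map <- function(object, slice = NULL, ...) {
  d <- dim(object$values)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(object$values[, , slice])
  df$x <- df$x * object$spacing[1]
  df$y <- df$y * object$spacing[2]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s %s (slice %d)", object$model, object$parameter, slice),
      x = "mm", y = "mm", fill = object$units
    )
}

#' ROC curve plot for one or more score sets
#'
#' @param scores Tibble with `score`, `label` and optionally grouping
#'   columns `map` and/or `method`.
#' @return A ggplot of ROC curves with the chance diagonal.
#' @export
plot_roc <- function(scores) {
  grp_cols <- intersect(c("map", "method"), names(scores))
  grouped <- if (length(grp_cols)) {
    dplyr::group_by(scores, dplyr::across(dplyr::all_of(grp_cols)))
  } else scores
  curves <- dplyr::reframe(grouped, roc_curve(.data$score, .data$label))
  curves$set <- if (length(grp_cols)) {
    do.call(paste, c(curves[grp_cols], sep = " / "))
  } else "scores"
  ggplot2::ggplot(curves, ggplot2::aes(x = 1 - .data$specificity,
                                       y = .data$sensitivity,
                                       colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL)
}

#' Top-n feature-importance bar chart
#'
#' The usual display of a random forest's mean-decrease-in-impurity
#' ranking (top 20 by default).
#'
#' @param importance Tibble from [feature_importance()].
#' @param top_n Number of leading features to show.
#' @return A ggplot horizontal bar chart.
#' @export
plot_importance <- function(importance, top_n = 20) {
  df <- dplyr::slice_head(importance, n = top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Mean decrease in impurity (normalised)", y = NULL)
}

#' AUC-with-CI dot plot for an evaluation report
#'
#' @param object An `eval_report` tibble.
#' @param ... Unused.
#' @return A ggplot point-range chart of AUC and its CI per map/method.
#' @exportS3Method autoplot eval_report
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$auc, y = .data$map,
                                       colour = .data$method)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$auc_lower, xmax = .data$auc_upper),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "AUC (95% CI)", y = NULL, colour = NULL)
}
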