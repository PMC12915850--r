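#' Plot a PCoA ordination
#'
#' @param object An `mgba_pcoa`.
#' @param colour Optional vector (aligned with the samples) used to colour
#'   points — typically study or case/control.
#' @param axes Which two axes to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mgba_pcoa <- function(object, colour = NULL, axes = c(1, 2), ...) {
  co <- object$coordinates
  ax <- paste0("Axis.", axes)
  ve <- object$variance_explained[axes] * 100
  df <- co
  if (!is.null(colour)) df$.colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]])) +
    ggplot2::labs(x = sprintf("%s (%.1f%%)", ax[1], ve[1]),
                  y = sprintf("%s (%.1f%%)", ax[2], ve[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$.colour)) +
      ggplot2::labs(colour = NULL)
  }
}

#' Plot nested-CV outer-fold AUROCs by repeat
#'
#' @param object A `nested_cv_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nested_cv_report <- function(object, ...) {
  ggplot2::ggplot(object$fold_metrics,
                  ggplot2::aes(factor(.data$repeat_id), .data$auroc)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = object$mean_auroc, linetype = 2) +
    ggplot2::labs(x = "repeat", y = "outer-fold AUROC") +
    ggplot2::theme_minimal()
}

#' Plot per-cohort LOCO AUROCs
#'
#' @param object A `loco_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.loco_report <- function(object, ...) {
  ggplot2::ggplot(object$per_cohort,
                  ggplot2::aes(.data$cohort, .data$auroc)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "held-out cohort", y = "AUROC") +
    ggplot2::theme_minimal()
}

#' Plot health-index distributions by group
#'
#' @param index Tibble from [index_for_dataset()].
#' @param labels 0/1 or logical case labels aligned with `index`.
#' @return A ggplot with the decision boundary at index 0.
#' @export
plot_index_distributions <- function(index, labels) {
  df <- dplyr::mutate(index,
                      group = ifelse(as.logical(labels), "disease", "healthy"))
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$index,
                                   fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.5) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(disease = "#e8a0b4",
                                          healthy = "#a8c8e8"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "MGBA-HI") +
    ggplot2::theme_minimal()
}
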