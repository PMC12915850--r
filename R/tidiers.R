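#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PERMANOVA result
#'
#' @param x A `permanova_result`.
#' @param ... Unused.
#' @return One-row tibble with term, df, sums of squares, R2, pseudo-F and
#'   the permutation p-value.
#' @export
tidy.permanova_result <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within"),
    df = c(x$df_between, x$df_within),
    sum_of_squares = c(x$ss_between, x$ss_within),
    r_squared = c(x$r_squared, 1 - x$r_squared),
    pseudo_f = c(x$pseudo_f, NA_real_),
    p_value = c(x$p_value, NA_real_)
  )
}

#' @rdname tidy.permanova_result
#' @export
glance.permanova_result <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, pseudo_f = x$pseudo_f,
                 p_value = x$p_value, n_permutations = x$n_permutations)
}

#' Tidy a nested-CV report
#'
#' @param x A `nested_cv_report`.
#' @param ... Unused.
#' @return The per-repeat per-fold AUROC tibble.
#' @export
tidy.nested_cv_report <- function(x, ...) x$fold_metrics

#' @rdname tidy.nested_cv_report
#' @export
glance.nested_cv_report <- function(x, ...) {
  tibble::tibble(mean_auroc = x$mean_auroc, sd_auroc = x$sd_auroc,
                 repeats = max(x$fold_metrics$repeat_id),
                 outer_folds = max(x$fold_metrics$fold),
                 family = x$spec$family)
}

#' Tidy a LOCO report
#'
#' @param x A `loco_report`.
#' @param ... Unused.
#' @return The per-cohort AUROC tibble.
#' @export
tidy.loco_report <- function(x, ...) x$per_cohort

#' @rdname tidy.loco_report
#' @export
glance.loco_report <- function(x, ...) {
  tibble::tibble(mean_auroc = x$mean_auroc,
                 n_cohorts = nrow(x$per_cohort), family = x$spec$family)
}

#' Tidy an index evaluation
#'
#' @param x An `index_evaluation`.
#' @param ... Unused.
#' @return The phenotype-correlation tibble (empty if no phenotypes), with
#'   the group test available via [glance()].
#' @export
tidy.index_evaluation <- function(x, ...) {
  x$phenotype_correlations %||% tibble::tibble()
}

#' @rdname tidy.index_evaluation
#' @export
glance.index_evaluation <- function(x, ...) x$group_test

#' Tidy a final model
#'
#' @param x An `mgba_final_model`.
#' @param ... Unused.
#' @return The feature-importance tibble of the fitted model.
#' @export
tidy.mgba_final_model <- function(x, ...) feature_importance(x$model)

#' @rdname tidy.mgba_final_model
#' @export
glance.mgba_final_model <- function(x, ...) {
  tibble::tibble(family = x$model$family, disease = x$disease,
                 n_features = length(x$features),
                 tuning_auroc = x$tuning_auroc,
                 final_fit_auroc = x$final_fit_auroc,
                 threshold = x$threshold)
}
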