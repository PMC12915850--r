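#' Tune and fit the final model
#'
#' Given a consensus feature set (typically [consensus_features()] of a
#' nested or LOCO report), runs a stratified 5-fold CV hyperparameter
#' search on the full data to pick the final hyperparameters (reporting the
#' tuning AUROC), then refits on all samples. The final-fit AUROC is a
#' resubstitution estimate and is optimistic by construction — the nested
#' and LOCO AUROCs remain the honest performance numbers.
#'
#' @param ds An [mgba_dataset()].
#' @param features Nonempty character vector of taxa the model may use.
#' @param spec A [model_spec()].
#' @param folds Tuning folds (default 5).
#' @param seed Seed for fold assignment and the search.
#' @return An object of class `mgba_final_model`: the fitted `model`,
#'   `features`, `params`, `tuning_auroc`, `final_fit_auroc`,
#'   `threshold` (`NA` until set by [youden_threshold()] on out-of-cohort
#'   probabilities), and `disease` (the training disease label).
#' @export
tune_final <- function(ds, features, spec, folds = 5, seed = 1) {
  stopifnot(length(features) > 0)
  x <- taxon_matrix(ds)[, features, drop = FALSE]
  y <- case_labels(ds)
  set.seed(substream_seed(seed, 7L))
  fold <- stratified_folds(y, folds)
  best_params <- default_params(spec)
  best_auc <- inner_cv_auroc(spec, x, y, fold, features, best_params)
  if (length(spec$ranges) > 0) {
    for (b in seq_len(spec$search_budget)) {
      cand <- sample_params(spec)
      a <- inner_cv_auroc(spec, x, y, fold, features, cand)
      if (a > best_auc) {
        best_auc <- a
        best_params <- cand
      }
    }
  }
  model <- fit_model(spec, x, y, best_params)
  fit_probs <- predict_prob(model, x)
  structure(list(
    model = model, features = features, params = best_params,
    tuning_auroc = best_auc,
    final_fit_auroc = auroc(fit_probs, y),
    threshold = NA_real_,
    disease = setdiff(unique(ds$samples$disease), ds$healthy_label)[1],
    spec = spec, seed = seed
  ), class = "mgba_final_model")
}

#' @export
print.mgba_final_model <- function(x, ...) {
  cat(sprintf("<mgba_final_model> %s for %s: %d features, tuning AUROC = %.3f, final-fit AUROC = %.3f (resubstitution, optimistic)\n",
              x$model$family, x$disease, length(x$features),
              x$tuning_auroc, x$final_fit_auroc))
  if (!is.na(x$threshold)) {
    cat(sprintf("  Youden-optimal probability threshold = %.3f\n", x$threshold))
  }
  invisible(x)
}

#' Predict disease probabilities on a dataset
#'
#' Taxa the model uses but the new profiles lack are imputed as zero (an
#' absent species is a meaningful zero in relative-abundance data); how
#' many were imputed is reported in a message.
#'
#' @param object An `mgba_final_model`.
#' @param ds An [mgba_dataset()] (or samples-by-taxa matrix).
#' @param ... Unused.
#' @return A tibble with `sample_id` and `probability`.
#' @export
predict.mgba_final_model <- function(object, ds, ...) {
  m <- if (inherits(ds, "mgba_dataset")) taxon_matrix(ds) else as.matrix(ds)
  missing_feats <- setdiff(object$features, colnames(m))
  if (length(missing_feats) > 0) {
    message(sprintf("predict: %d model feature(s) absent from profiles, imputed as 0",
                    length(missing_feats)))
    pad <- matrix(0, nrow(m), length(missing_feats),
                  dimnames = list(rownames(m), missing_feats))
    m <- cbind(m, pad)
  }
  tibble::tibble(sample_id = rownames(m),
                 probability = predict_prob(object$model, m))
}

#' Cross-study generalization matrix
#'
#' Trains one final model per study of the same disease (with features and
#' hyperparameters chosen by per-study nested CV) and scores each model on
#' every other study. The diagonal holds each study's own nested-CV AUROC;
#' off-diagonal entries measure transfer to unseen studies.
#'
#' @param ds A multi-study [mgba_dataset()] of one disease (at least 2
#'   studies).
#' @param spec A [model_spec()].
#' @param repeats Nested-CV repeats for the diagonal (default 3 here:
#'   per-study data is small and the matrix grows quadratically).
#' @param outer_folds,inner_folds Fold counts.
#' @param seed Seed.
#' @return A list of class `cross_study_matrix`: `auroc_matrix`
#'   (train-study x test-study), `mean_diagonal`, `mean_off_diagonal`.
#' @export
cross_study_validation <- function(ds, spec, repeats = 3, outer_folds = 5,
                                   inner_folds = 5, seed = 1) {
  studies <- unique(ds$samples$study_id)
  if (length(studies) < 2) stop("need at least 2 studies", call. = FALSE)
  k <- length(studies)
  mat <- matrix(NA_real_, k, k, dimnames = list(train = studies,
                                                test = studies))
  for (i in seq_len(k)) {
    tr_ds <- subset_samples(ds, ds$samples$study_id == studies[i])
    report <- nested_cv(tr_ds, spec, repeats = repeats,
                        outer_folds = outer_folds,
                        inner_folds = inner_folds,
                        seed = substream_seed(seed, i))
    mat[i, i] <- report$mean_auroc
    final <- tune_final(tr_ds, consensus_features(report), spec,
                        seed = substream_seed(seed, i))
    for (j in setdiff(seq_len(k), i)) {
      te_ds <- subset_samples(ds, ds$samples$study_id == studies[j])
      pr <- predict(final, te_ds)
      mat[i, j] <- auroc(pr$probability, case_labels(te_ds))
    }
  }
  off <- mat
  diag(off) <- NA
  structure(list(auroc_matrix = mat,
                 mean_diagonal = mean(diag(mat)),
                 mean_off_diagonal = mean(off, na.rm = TRUE)),
            class = "cross_study_matrix")
}

#' @export
print.cross_study_matrix <- function(x, ...) {
  cat(sprintf("<cross_study_matrix> mean diagonal (own nested CV) = %.3f, mean off-diagonal (transfer) = %.3f\n",
              x$mean_diagonal, x$mean_off_diagonal))
  print(round(x$auroc_matrix, 3))
  invisible(x)
}

#' Cross-disease specificity of a final model
#'
#' Applies a trained disease model to datasets of entirely different
#' diseases. A specific model should perform near chance (AUROC around
#' 0.5) on foreign diseases whose microbial signatures it never learned.
#'
#' @param final_model An `mgba_final_model`.
#' @param other_disease_datasets Named list of [mgba_dataset()]s with
#'   disease labels disjoint from the training disease.
#' @return A tibble with `disease` and `auroc`.
#' @export
cross_disease_specificity <- function(final_model, other_disease_datasets) {
  purrr::map_dfr(other_disease_datasets, function(ds) {
    dis <- setdiff(unique(ds$samples$disease), ds$healthy_label)[1]
    pr <- suppressMessages(predict(final_model, ds))
    tibble::tibble(disease = dis,
                   auroc = auroc(pr$probability, case_labels(ds)))
  })
}
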