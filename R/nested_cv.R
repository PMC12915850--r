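## Stratified k-fold assignment: within each class, samples are shuffled
## (ordered by group first when `group` is given, to spread cohorts across
## folds) and dealt round-robin, so every fold's class ratio is within one
## sample of the global ratio.
stratified_folds <- function(y, k, group = NULL) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    if (!is.null(group)) idx <- idx[order(group[idx])]
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

## Outer folds must contain both classes; re-deal on failure, error after
## 10 attempts.
outer_folds_checked <- function(y, k, attempts = 10) {
  for (a in seq_len(attempts)) {
    fold <- stratified_folds(y, k)
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(y[fold == f])) == 2
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("could not build outer folds with both classes in every fold",
       call. = FALSE)
}

## Univariate discriminative score per feature: |AUROC - 0.5|, rank-based.
univariate_auc_scores <- function(x, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- apply(x, 2, rank)
  auc <- (colSums(r[y == 1, , drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  abs(auc - 0.5)
}

## Mid-range default hyperparameters of a spec (log-mid for log-scaled).
default_params <- function(spec) {
  log_scale <- c("lambda", "learning_rate")
  int_valued <- c("depth", "iterations", "min_node_size", "num_trees")
  out <- lapply(names(spec$ranges), function(nm) {
    r <- spec$ranges[[nm]]
    v <- if (nm %in% log_scale) exp(mean(log(r))) else mean(r)
    if (nm %in% int_valued) v <- as.integer(round(v))
    v
  })
  stats::setNames(out, names(spec$ranges))
}

## Pooled out-of-fold AUROC of (features, params) under an inner-fold
## assignment.
inner_cv_auroc <- function(spec, x, y, fold, features, params) {
  probs <- numeric(length(y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    model <- fit_model(spec, x[tr, features, drop = FALSE], y[tr], params)
    probs[!tr] <- predict_prob(model, x[!tr, features, drop = FALSE])
  }
  auroc(probs, y)
}

## The inner loop: on training data only, (a) rank features univariately,
## (b) pick top-k over the spec's k-grid by inner-CV AUROC, (c) random-
## search hyperparameters at the spec's budget by inner-CV AUROC, then fit
## the winning configuration on all training data.
inner_select_and_fit <- function(spec, x, y, inner_folds, group = NULL) {
  fold <- stratified_folds(y, inner_folds, group = group)
  scores <- univariate_auc_scores(x, y)
  ranked <- colnames(x)[order(scores, decreasing = TRUE)]
  ks <- unique(pmin(spec$feature_grid, ncol(x)))
  base <- default_params(spec)
  k_auc <- vapply(ks, function(k) {
    inner_cv_auroc(spec, x, y, fold, ranked[seq_len(k)], base)
  }, numeric(1))
  best_k <- ks[which.max(k_auc)]
  features <- ranked[seq_len(best_k)]
  best_params <- base
  best_auc <- max(k_auc)
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
  model <- fit_model(spec, x[, features, drop = FALSE], y, best_params)
  list(model = model, features = features, params = best_params,
       inner_auroc = best_auc)
}

#' Repeated nested cross-validation
#'
#' Unbiased performance estimation for microbiome classifiers: an outer
#' stratified k-fold loop measures performance while an inner k-fold loop —
#' run on the outer-training portion only — performs univariate-AUC feature
#' ranking, top-k selection over a size grid, and random-search
#' hyperparameter tuning at the spec's budget. No statistic computed on a
#' held-out fold ever influences selection, which is the property that
#' keeps the outer estimate honest.
#'
#' @param ds An [mgba_dataset()]; `is_case` is the label.
#' @param spec A [model_spec()].
#' @param repeats Outer repetitions (default 10).
#' @param outer_folds,inner_folds Fold counts (default 5 and 5).
#' @param seed Seed fixing fold assignments, feature selection and tuning.
#' @return An object of class `nested_cv_report`: `fold_metrics` (tibble of
#'   `repeat_id`, `fold`, `auroc`, `n_features`), `oof` (out-of-fold
#'   probabilities: `repeat_id`, `sample_id`, `probability`, `label`),
#'   `selected_features` (list per repeat x fold), `chosen_params`,
#'   `mean_auroc` (grand mean over outer test folds), `sd_auroc` (sd of the
#'   per-repeat means).
#' @export
nested_cv <- function(ds, spec, repeats = 10, outer_folds = 5,
                      inner_folds = 5, seed = 1) {
  x <- taxon_matrix(ds)
  y <- case_labels(ds)
  nested_cv_xy(x, y, spec, repeats, outer_folds, inner_folds, seed,
               sample_ids = ds$profiles$sample_id)
}

nested_cv_xy <- function(x, y, spec, repeats, outer_folds, inner_folds, seed,
                         sample_ids = rownames(x)) {
  if (length(unique(y)) < 2) stop("both classes required", call. = FALSE)
  metrics <- list()
  oof <- list()
  selected <- list()
  params_log <- list()
  for (r in seq_len(repeats)) {
    set.seed(substream_seed(seed, r))
    fold <- outer_folds_checked(y, outer_folds)
    probs <- numeric(length(y))
    for (f in seq_len(outer_folds)) {
      tr <- fold != f
      sel <- inner_select_and_fit(spec, x[tr, , drop = FALSE], y[tr],
                                  inner_folds)
      p_held <- predict_prob(sel$model, x[!tr, , drop = FALSE])
      probs[!tr] <- p_held
      metrics[[length(metrics) + 1]] <- tibble::tibble(
        repeat_id = r, fold = f, auroc = auroc(p_held, y[!tr]),
        n_features = length(sel$features)
      )
      key <- sprintf("r%02d_f%d", r, f)
      selected[[key]] <- sel$features
      params_log[[key]] <- sel$params
    }
    oof[[r]] <- tibble::tibble(repeat_id = r, sample_id = sample_ids,
                               probability = probs, label = y)
  }
  fold_metrics <- dplyr::bind_rows(metrics)
  per_repeat <- dplyr::summarise(dplyr::group_by(fold_metrics, .data$repeat_id),
                                 auroc = mean(.data$auroc), .groups = "drop")
  structure(list(
    fold_metrics = fold_metrics,
    oof = dplyr::bind_rows(oof),
    selected_features = selected,
    chosen_params = params_log,
    mean_auroc = mean(fold_metrics$auroc),
    sd_auroc = stats::sd(per_repeat$auroc),
    spec = spec, seed = seed
  ), class = "nested_cv_report")
}

#' @export
print.nested_cv_report <- function(x, ...) {
  cat(sprintf("<nested_cv_report> %s: mean nested AUROC = %.3f (sd %.3f over %d repeats)\n",
              x$spec$family, x$mean_auroc, x$sd_auroc,
              max(x$fold_metrics$repeat_id)))
  invisible(x)
}

#' Leave-one-cohort-out cross-validation
#'
#' For datasets pooling three or more cohorts, each outer iteration holds
#' out one whole cohort; the inner k-fold loop on the remaining cohorts
#' performs the same feature selection and hyperparameter tuning as
#' [nested_cv()]. Every sample's probability comes from a model that never
#' saw its cohort. A held-out cohort lacking one class still receives
#' probabilities but its AUROC is reported `NA`; at least three cohorts
#' containing both classes are required.
#'
#' @inheritParams nested_cv
#' @return An object of class `loco_report`: `per_cohort` (tibble of
#'   `cohort`, `auroc`, `n`, `n_features`), `oof` (per-sample out-of-cohort
#'   probabilities), `selected_features` and `chosen_params` per cohort,
#'   `mean_auroc`.
#' @export
loco_cv <- function(ds, spec, inner_folds = 5, seed = 1) {
  x <- taxon_matrix(ds)
  y <- case_labels(ds)
  cohort <- as.character(ds$samples$study_id)
  usable <- vapply(unique(cohort), function(s) {
    length(unique(y[cohort == s])) == 2
  }, logical(1))
  if (sum(usable) < 3) {
    stop("LOCO needs at least 3 cohorts containing both classes", call. = FALSE)
  }
  metrics <- list()
  oof <- list()
  selected <- list()
  params_log <- list()
  for (i in seq_along(unique(cohort))) {
    s <- unique(cohort)[i]
    set.seed(substream_seed(seed, 100L + i))
    held <- cohort == s
    sel <- inner_select_and_fit(spec, x[!held, , drop = FALSE], y[!held],
                                inner_folds, group = cohort[!held])
    p_held <- predict_prob(sel$model, x[held, , drop = FALSE])
    auc_s <- if (length(unique(y[held])) == 2) auroc(p_held, y[held]) else NA_real_
    metrics[[s]] <- tibble::tibble(cohort = s, auroc = auc_s,
                                   n = sum(held),
                                   n_features = length(sel$features))
    oof[[s]] <- tibble::tibble(sample_id = ds$profiles$sample_id[held],
                               cohort = s, probability = p_held,
                               label = y[held])
    selected[[s]] <- sel$features
    params_log[[s]] <- sel$params
  }
  per_cohort <- dplyr::bind_rows(metrics)
  structure(list(
    per_cohort = per_cohort,
    oof = dplyr::bind_rows(oof),
    selected_features = selected,
    chosen_params = params_log,
    mean_auroc = mean(per_cohort$auroc, na.rm = TRUE),
    spec = spec, seed = seed
  ), class = "loco_report")
}

#' @export
print.loco_report <- function(x, ...) {
  cat(sprintf("<loco_report> %s: mean per-cohort AUROC = %.3f over %d cohorts\n",
              x$spec$family, x$mean_auroc, nrow(x$per_cohort)))
  print(x$per_cohort)
  invisible(x)
}

#' Consensus feature set across CV folds
#'
#' Features selected in at least `threshold` of the outer folds (or
#' held-out cohorts) of a report — the default aggregation feeding
#' [tune_final()].
#'
#' @param report A `nested_cv_report` or `loco_report`.
#' @param threshold Minimum selection frequency (default 0.5).
#' @return Character vector of feature names.
#' @export
consensus_features <- function(report, threshold = 0.5) {
  sets <- report$selected_features
  freq <- table(unlist(sets)) / length(sets)
  out <- names(freq)[freq >= threshold]
  if (length(out) == 0) {
    # fall back to the most frequently selected features
    out <- names(sort(freq, decreasing = TRUE))[seq_len(min(16, length(freq)))]
  }
  out
}
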