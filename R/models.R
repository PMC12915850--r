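#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a randomly chosen
#' positive scores above a randomly chosen negative, with ties counted half.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels 0/1 (or logical) labels, 1 = case.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Specify a classification model family and its search space
#'
#' @param family One of `"lasso_logistic"`, `"elastic_net"`, `"logistic"`,
#'   `"random_forest"`, `"gradient_boosting"`. Gradient boosting uses the
#'   conventional tree-boosting ranges: depth 4-12, learning rate 0.01-0.3,
#'   100-1000 boosting iterations, L2 leaf regularization 1-20.
#' @param ranges Optional named list overriding the family's hyperparameter
#'   ranges (each a length-2 numeric `c(lo, hi)`).
#' @param search_budget Hyperparameter draws evaluated per tuning run.
#' @param feature_grid Candidate top-k feature-set sizes scanned by the
#'   inner loop (`Inf` = all features).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("lasso_logistic", "elastic_net", "logistic",
                                  "random_forest", "gradient_boosting"),
                       ranges = NULL, search_budget = 30,
                       feature_grid = c(16, 32, 64, 128, Inf)) {
  family <- match.arg(family)
  defaults <- switch(family,
    lasso_logistic = list(lambda = c(1e-3, 1)),
    elastic_net = list(alpha = c(0.05, 1), lambda = c(1e-3, 1)),
    logistic = list(),
    random_forest = list(mtry_frac = c(0.05, 1), min_node_size = c(1, 10),
                         num_trees = c(200, 200)),
    gradient_boosting = list(depth = c(4, 12), learning_rate = c(0.01, 0.3),
                             iterations = c(100, 1000),
                             l2_leaf_reg = c(1, 20))
  )
  if (!is.null(ranges)) defaults[names(ranges)] <- ranges
  for (r in defaults) stopifnot(length(r) == 2, r[1] <= r[2])
  stopifnot(search_budget >= 1)
  structure(list(family = family, ranges = defaults,
                 search_budget = search_budget,
                 feature_grid = sort(unique(feature_grid))),
            class = "model_spec")
}

## Draw one hyperparameter setting uniformly from the spec's ranges
## (log-uniform for the penalty/learning-rate scales).
sample_params <- function(spec) {
  log_scale <- c("lambda", "learning_rate")
  int_valued <- c("depth", "iterations", "min_node_size", "num_trees")
  out <- lapply(names(spec$ranges), function(nm) {
    r <- spec$ranges[[nm]]
    v <- if (nm %in% log_scale) {
      exp(stats::runif(1, log(r[1]), log(r[2])))
    } else {
      stats::runif(1, r[1], r[2])
    }
    if (nm %in% int_valued) v <- as.integer(round(v))
    v
  })
  stats::setNames(out, names(spec$ranges))
}

## Fit one model of the spec's family on a numeric matrix.
fit_model <- function(spec, x, y, params) {
  family <- spec$family
  y <- as.numeric(y)
  fit <- switch(family,
    logistic = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    lasso_logistic = ,
    elastic_net = {
      alpha <- if (family == "lasso_logistic") 1 else params$alpha
      if (ncol(x) < 2) {
        df <- data.frame(.y = y, x, check.names = FALSE)
        suppressWarnings(stats::glm(.y ~ ., data = df,
                                    family = stats::binomial()))
      } else {
        # aggressive lambda draws from the search can fail to converge at
        # maxit; glmnet falls back to the larger-lambda solution, which the
        # inner-CV score then judges on its merits
        suppressWarnings(
          glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                         lambda = params$lambda, standardize = TRUE)
        )
      }
    },
    random_forest = {
      mtry <- max(1, round(params$mtry_frac * ncol(x)))
      ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                     probability = TRUE, num.trees = params$num_trees,
                     mtry = min(mtry, ncol(x)),
                     min.node.size = params$min_node_size,
                     importance = "impurity", num.threads = 1,
                     seed = sample.int(.Machine$integer.max, 1))
    },
    gradient_boosting = {
      xgboost::xgboost(data = x, label = y,
                       objective = "binary:logistic",
                       nrounds = params$iterations,
                       max_depth = params$depth, eta = params$learning_rate,
                       lambda = params$l2_leaf_reg,
                       nthread = 1, verbose = 0)
    }
  )
  structure(list(family = family, fit = fit, params = params,
                 features = colnames(x)),
            class = "mgba_model")
}

## Predicted case probability on a numeric matrix with matching columns.
predict_prob <- function(model, x) {
  x <- x[, model$features, drop = FALSE]
  fit <- model$fit
  switch(model$family,
    logistic = {
      nd <- as.data.frame(x, check.names = FALSE)
      as.numeric(stats::predict(fit, newdata = nd, type = "response"))
    },
    lasso_logistic = ,
    elastic_net = {
      if (inherits(fit, "glm")) {
        nd <- as.data.frame(x, check.names = FALSE)
        as.numeric(stats::predict(fit, newdata = nd, type = "response"))
      } else {
        as.numeric(stats::predict(fit, newx = x, type = "response"))
      }
    },
    random_forest = {
      stats::predict(fit, data = x, num.threads = 1)$predictions[, "1"]
    },
    gradient_boosting = {
      as.numeric(stats::predict(fit, newdata = x))
    }
  )
}

#' Feature importance of a fitted model
#'
#' Dispatches on the model family: absolute coefficient values for the
#' linear families (lasso, elastic net, plain logistic), mean decrease in
#' impurity (Gini importance) for random forests, and total split gain — a
#' prediction-value-change analogue — for gradient boosting.
#'
#' @param model A fitted model as stored in the reports of [nested_cv()],
#'   [loco_cv()] or [tune_final()].
#' @return A tibble with `taxon`, `importance` (raw, nonnegative for the
#'   coefficient and impurity rules), `normalized` (sums to 1 when any
#'   importance is nonzero) and `rule`.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "mgba_model")) {
    stop("not a fitted model", call. = FALSE)
  }
  fit <- model$fit
  features <- model$features
  imp <- stats::setNames(numeric(length(features)), features)
  rule <- switch(model$family,
    logistic = , lasso_logistic = , elastic_net = "abs_coefficient",
    random_forest = "impurity_decrease",
    gradient_boosting = "prediction_value_change")
  if (rule == "abs_coefficient") {
    co <- if (inherits(fit, "glm")) stats::coef(fit) else {
      drop(as.matrix(stats::coef(fit)))
    }
    co <- co[setdiff(names(co), "(Intercept)")]
    names(co) <- gsub("^`|`$", "", names(co))
    imp[names(co)] <- abs(co)
  } else if (rule == "impurity_decrease") {
    ri <- ranger::importance(fit)
    imp[names(ri)] <- ri
  } else {
    gain <- xgboost::xgb.importance(model = fit)
    imp[gain$Feature] <- gain$Gain
  }
  tot <- sum(imp)
  tibble::tibble(taxon = features, importance = unname(imp),
                 normalized = if (tot > 0) unname(imp) / tot else 0,
                 rule = rule)
}
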