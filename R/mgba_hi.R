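#' Youden-optimal probability threshold
#'
#' Scans every candidate cut of the predicted probabilities (midpoints
#' between adjacent sorted unique values, plus cuts below and above the
#' observed range) and returns the one maximizing Youden's index
#' `J(t) = sensitivity(t) + specificity(t) - 1`, where a sample is
#' predicted positive when its probability is at least `t`. Ties in `J`
#' are broken toward higher sensitivity (the lower threshold). Returning a
#' midpoint rather than an observed value makes the cut stable under
#' infinitesimal score perturbations.
#'
#' @param probabilities Predicted disease probabilities in `[0, 1]`.
#' @param labels 0/1 (or logical) labels, 1 = case. Both classes required.
#' @return The optimal threshold, strictly inside `(0, 1)`.
#' @export
youden_threshold <- function(probabilities, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("both classes required", call. = FALSE)
  stopifnot(all(probabilities >= 0), all(probabilities <= 1))
  u <- sort(unique(probabilities))
  cuts <- c((u[1] + 0) / 2, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            (u[length(u)] + 1) / 2)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  j <- vapply(cuts, function(t) {
    sens <- sum(probabilities >= t & labels == 1) / n1
    spec <- sum(probabilities < t & labels == 0) / n0
    sens + spec - 1
  }, numeric(1))
  best <- cuts[j >= max(j) - 1e-12]
  t_star <- min(best)  # ties broken toward higher sensitivity
  min(max(t_star, .Machine$double.eps), 1 - .Machine$double.eps)
}

#' Microbial gut-brain axis health index
#'
#' `MGBA-HI = threshold - probability`: the predicted disease probability
#' reflected around the Youden-optimal decision boundary, so that 0 marks
#' the boundary, positive values a healthy-like profile
#' (probability below the threshold), and negative values a disease-like
#' profile, with magnitude quantifying confidence.
#'
#' @param probability Predicted disease probability in `[0, 1]`.
#' @param threshold Optimal classification threshold from
#'   [youden_threshold()].
#' @return The index value (vectorized over `probability`).
#' @examples
#' mgba_hi(c(0, 0.37, 1), threshold = 0.37)
#' @export
mgba_hi <- function(probability, threshold) {
  stopifnot(all(probability >= 0), all(probability <= 1),
            threshold > 0, threshold < 1)
  threshold - probability
}

#' Per-sample health index for a dataset
#'
#' Training-population samples are scored with their out-of-cohort
#' probability from a [loco_cv()] report (never a self-prediction);
#' external samples are scored by a final model. The threshold defaults to
#' the Youden optimum of the LOCO out-of-cohort probabilities.
#'
#' @param ds An [mgba_dataset()].
#' @param loco_report A `loco_report` covering the training samples
#'   (optional if `final_model` is given and covers all of `ds`).
#' @param final_model An `mgba_final_model` for samples absent from the
#'   LOCO report (optional).
#' @param threshold Probability threshold; by default computed from the
#'   LOCO report's out-of-cohort probabilities (or, failing that, from the
#'   final model's predictions on `ds`).
#' @return A tibble with `sample_id`, `probability`, `source`
#'   (`"out_of_cohort"` or `"final_model"`), `index`, plus the threshold as
#'   attribute `"threshold"`.
#' @export
index_for_dataset <- function(ds, loco_report = NULL, final_model = NULL,
                              threshold = NULL) {
  ids <- ds$profiles$sample_id
  prob <- rep(NA_real_, length(ids))
  source <- rep(NA_character_, length(ids))
  if (!is.null(loco_report)) {
    hit <- match(ids, loco_report$oof$sample_id)
    got <- !is.na(hit)
    prob[got] <- loco_report$oof$probability[hit[got]]
    source[got] <- "out_of_cohort"
  }
  need <- is.na(prob)
  if (any(need)) {
    if (is.null(final_model)) {
      stop(sprintf("%d sample(s) have neither an out-of-cohort probability nor a final model",
                   sum(need)), call. = FALSE)
    }
    pr <- predict(final_model, subset_samples(ds, need))
    prob[need] <- pr$probability
    source[need] <- "final_model"
  }
  if (is.null(threshold)) {
    threshold <- if (!is.null(loco_report)) {
      youden_threshold(loco_report$oof$probability, loco_report$oof$label)
    } else {
      youden_threshold(prob, case_labels(ds))
    }
  }
  out <- tibble::tibble(sample_id = ids, probability = prob,
                        source = source,
                        index = mgba_hi(prob, threshold))
  attr(out, "threshold") <- threshold
  out
}

#' Cliff's delta effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (|x| |y|)` over all pairs.
#' With `x` the disease values and `y` the health values, negative delta
#' means the quantity is lower in patients.
#'
#' @param x Disease-group values.
#' @param y Health-group values.
#' @return Delta in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  r <- rank(c(x, y))
  rx <- r[seq_along(x)]
  nx <- length(x)
  ny <- length(y)
  # sum of "wins" of x over y with ties counting half, via midranks
  wins <- sum(rx) - nx * (nx + 1) / 2
  (2 * wins - nx * ny) / (nx * ny)
}

#' Evaluate a health index against labels and phenotypes
#'
#' Compares the index between cases and controls with a two-sided Wilcoxon
#' rank-sum test and Cliff's delta (disease vs health), and correlates the
#' index with each phenotype by Spearman's rho with a percentile-bootstrap
#' confidence interval.
#'
#' @param index Per-sample index values.
#' @param labels 0/1 (or logical), 1 = case.
#' @param phenotypes Optional data frame / tibble of numeric phenotype
#'   columns aligned with `index` (at least 5 complete pairs per
#'   phenotype).
#' @param n_boot Bootstrap resamples for the correlation CIs (default
#'   10000).
#' @param conf_level CI level (default 0.95).
#' @param seed Optional bootstrap seed.
#' @return A list of class `index_evaluation`: `group_test` (one-row tibble
#'   with medians, `wilcoxon_p`, `cliffs_delta`, `degenerate`) and
#'   `phenotype_correlations` (tibble with `phenotype`, `rho`, `ci_lower`,
#'   `ci_upper`, `p`, `n`).
#' @export
evaluate_index <- function(index, labels, phenotypes = NULL, n_boot = 10000,
                           conf_level = 0.95, seed = NULL) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("both classes required", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- index[labels == 1]
  y <- index[labels == 0]
  degenerate <- length(unique(index)) == 1
  w_p <- if (degenerate) 1 else {
    stats::wilcox.test(x, y, exact = FALSE)$p.value
  }
  group_test <- tibble::tibble(
    median_case = stats::median(x), median_control = stats::median(y),
    wilcoxon_p = w_p, cliffs_delta = cliffs_delta(x, y),
    degenerate = degenerate
  )
  pheno_tbl <- NULL
  if (!is.null(phenotypes)) {
    phenotypes <- tibble::as_tibble(phenotypes)
    alpha <- (1 - conf_level) / 2
    pheno_tbl <- purrr::map_dfr(names(phenotypes), function(ph) {
      v <- as.numeric(phenotypes[[ph]])
      ok <- !is.na(v) & !is.na(index)
      n <- sum(ok)
      if (n < 5) {
        return(tibble::tibble(phenotype = ph, rho = NA_real_,
                              ci_lower = NA_real_, ci_upper = NA_real_,
                              p = NA_real_, n = n))
      }
      iv <- index[ok]; pv <- v[ok]
      if (stats::sd(iv) == 0 || stats::sd(pv) == 0) {
        return(tibble::tibble(phenotype = ph, rho = NA_real_,
                              ci_lower = NA_real_, ci_upper = NA_real_,
                              p = NA_real_, n = n))
      }
      ct <- suppressWarnings(stats::cor.test(iv, pv, method = "spearman"))
      boots <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        if (stats::sd(iv[idx]) == 0 || stats::sd(pv[idx]) == 0) return(NA_real_)
        stats::cor(iv[idx], pv[idx], method = "spearman")
      }, numeric(1))
      ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE,
                            names = FALSE)
      tibble::tibble(phenotype = ph, rho = unname(ct$estimate),
                     ci_lower = ci[1], ci_upper = ci[2],
                     p = ct$p.value, n = n)
    })
  }
  structure(list(group_test = group_test,
                 phenotype_correlations = pheno_tbl),
            class = "index_evaluation")
}

#' @export
print.index_evaluation <- function(x, ...) {
  g <- x$group_test
  cat(sprintf("index: case median %.3f vs control median %.3f; rank-sum p = %.3g; Cliff's delta = %.3f%s\n",
              g$median_case, g$median_control, g$wilcoxon_p, g$cliffs_delta,
              if (g$degenerate) " (degenerate: constant index)" else ""))
  if (!is.null(x$phenotype_correlations)) print(x$phenotype_correlations)
  invisible(x)
}
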