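#' Empirical-Bayes batch correction of log abundances
#'
#' Covariate-preserving batch correction of the ComBat family, operating on
#' `y = log10(abundance + pseudocount)`. Per taxon, a linear model with
#' batch indicators and the case/control covariate is fit; residual variance
#' is standardized; per-batch location and scale effects are shrunk by
#' empirical Bayes (normal prior on locations, inverse-gamma prior on
#' scales, hyperparameters moment-matched across taxa); the shrunken batch
#' effects are removed and the covariate fit and grand mean restored.
#' Back-transformed abundances are clipped at zero. Compositions are
#' deliberately not re-closed after correction (set `reclose = TRUE` for the
#' alternative).
#'
#' @param ds An [mgba_dataset()] with at least two studies (batches), each
#'   containing at least two samples and both cases and controls (a batch
#'   perfectly confounded with the covariate cannot be corrected and raises
#'   an error naming it).
#' @param covariate Column of `ds$samples` holding the biological signal to
#'   preserve. Default `"is_case"`.
#' @param pseudocount Added before the log10 transform. Default half the
#'   1e-4 abundance detection limit.
#' @param parametric Use the parametric (normal / inverse-gamma) empirical
#'   Bayes shrinkage (default); `FALSE` selects the non-parametric variant,
#'   which weights each taxon's batch-effect estimate by the empirical prior
#'   formed from all other taxa.
#' @param reclose Re-normalize each corrected sample to its original taxon
#'   total (preserving the unclassified remainder).
#' @return An object of class `batch_correction`: `dataset` (corrected
#'   `mgba_dataset`), `location` and `scale` (batch-by-taxon matrices of
#'   shrunken effects), `pseudocount`.
#' @export
eb_batch_correct <- function(ds, covariate = "is_case", pseudocount = 5e-5,
                             parametric = TRUE, reclose = FALSE) {
  batch <- as.character(ds$samples$study_id)
  batches <- unique(batch)
  if (length(batches) < 2) stop("need at least 2 batches to correct", call. = FALSE)
  if (any(table(batch) < 2)) stop("every batch needs at least 2 samples", call. = FALSE)
  cov <- ds$samples[[covariate]]
  if (is.null(cov)) stop("covariate column not found: ", covariate, call. = FALSE)
  cov <- as.numeric(cov)
  for (b in batches) {
    if (length(unique(cov[batch == b])) < 2) {
      stop(sprintf("batch '%s' is confounded with the covariate (one class only)", b),
           call. = FALSE)
    }
  }
  m <- taxon_matrix(ds)
  y <- t(log10(m + pseudocount))          # taxa x samples
  n <- ncol(y)
  bd <- stats::model.matrix(~ 0 + factor(batch, levels = batches))
  colnames(bd) <- batches
  design <- cbind(bd, covariate = cov)
  n_batches <- colSums(bd)

  b_hat <- solve(crossprod(design), crossprod(design, t(y)))  # coef x taxa
  grand_mean <- crossprod(n_batches / n, b_hat[seq_along(batches), , drop = FALSE])
  resid <- y - t(design %*% b_hat)
  var_pooled <- rowMeans(resid^2)
  keep <- var_pooled > 1e-12              # constant taxa pass through untouched
  stand_mean <- matrix(grand_mean, nrow(y), n) +
    t(design[, -seq_along(batches), drop = FALSE] %*%
        b_hat[-seq_along(batches), , drop = FALSE])
  s <- (y - stand_mean) / sqrt(var_pooled)
  s[!keep, ] <- 0

  gamma_hat <- matrix(0, length(batches), nrow(y),
                      dimnames = list(batches, rownames(y)))
  delta_hat <- gamma_hat
  for (i in seq_along(batches)) {
    idx <- batch == batches[i]
    gamma_hat[i, ] <- rowMeans(s[, idx, drop = FALSE])
    delta_hat[i, ] <- pmax(apply(s[, idx, drop = FALSE], 1, stats::var), 1e-8)
  }
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (i in seq_along(batches)) {
    idx <- which(batch == batches[i])
    g_hat <- gamma_hat[i, keep]
    d_hat <- delta_hat[i, keep]
    sub <- s[keep, idx, drop = FALSE]
    if (parametric) {
      est <- eb_parametric(sub, g_hat, d_hat)
    } else {
      est <- eb_nonparametric(sub, g_hat, d_hat)
    }
    gamma_star[i, keep] <- est$gamma
    delta_star[i, keep] <- est$delta
    s[keep, idx] <- (sub - est$gamma) / sqrt(est$delta)
  }
  y_adj <- s * sqrt(var_pooled) + stand_mean
  y_adj[!keep, ] <- y[!keep, ]
  corrected <- pmax(t(10^y_adj) - pseudocount, 0)
  if (reclose) {
    target <- rowSums(m)
    tot <- rowSums(corrected)
    nz <- tot > 0
    corrected[nz, ] <- corrected[nz, , drop = FALSE] * (target[nz] / tot[nz])
  }
  structure(list(dataset = set_taxon_matrix(ds, corrected),
                 location = gamma_star, scale = delta_star,
                 pseudocount = pseudocount),
            class = "batch_correction")
}

## Parametric EB: normal prior on locations, inverse-gamma on scales,
## moment-matched hyperparameters; fixed-point iteration for the joint
## posterior modes.
eb_parametric <- function(s_batch, g_hat, d_hat, tol = 1e-4, max_iter = 100) {
  nb <- ncol(s_batch)
  g_bar <- mean(g_hat)
  t2 <- stats::var(g_hat)
  m <- mean(d_hat)
  s2 <- stats::var(d_hat)
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2
  g_old <- g_hat
  d_old <- d_hat
  for (it in seq_len(max_iter)) {
    g_new <- (t2 * nb * g_hat + d_old * g_bar) / (t2 * nb + d_old)
    sum2 <- rowSums((s_batch - g_new)^2)
    d_new <- (0.5 * sum2 + b_prior) / (nb / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                  abs(d_new - d_old) / abs(d_old + 1e-12))
    g_old <- g_new
    d_old <- d_new
    if (change < tol) break
  }
  list(gamma = g_old, delta = pmax(d_old, 1e-8))
}

## Non-parametric EB: each taxon's (location, scale) posterior is the
## likelihood-weighted average of all other taxa's raw estimates.
eb_nonparametric <- function(s_batch, g_hat, d_hat) {
  p <- nrow(s_batch)
  nb <- ncol(s_batch)
  gamma <- g_hat
  delta <- d_hat
  for (g in seq_len(p)) {
    others <- setdiff(seq_len(p), g)
    x <- s_batch[g, ]
    # log-likelihood of taxon g's standardized data under each other taxon's
    # batch-effect estimate
    sum2 <- vapply(others, function(o) sum((x - g_hat[o])^2), numeric(1))
    ll <- -nb / 2 * log(2 * pi * d_hat[others]) - sum2 / (2 * d_hat[others])
    w <- exp(ll - max(ll))
    w <- w / sum(w)
    gamma[g] <- sum(w * g_hat[others])
    delta[g] <- sum(w * d_hat[others])
  }
  list(gamma = gamma, delta = pmax(delta, 1e-8))
}

#' Batch-variance reduction achieved by a correction
#'
#' Quantifies how much of the batch signal a correction removed:
#' `100 * (R2_before - R2_after) / R2_before`, where each `R2` is the
#' PERMANOVA variance fraction explained by study membership on Bray-Curtis
#' dissimilarities.
#'
#' @param before,after The same samples as [mgba_dataset()]s, pre- and
#'   post-correction (the `after` may come from any corrector, not just
#'   [eb_batch_correct()]).
#' @param n_permutations Permutations for each PERMANOVA (default 999).
#' @param seed Optional permutation seed.
#' @return A list with `reduction_pct`, `r2_before`, `r2_after` and the two
#'   `permanova_result` objects. `reduction_pct` is `NA` when the
#'   pre-correction batch R2 is zero.
#' @export
batch_variance_reduction <- function(before, after, n_permutations = 999,
                                     seed = NULL) {
  stopifnot(identical(before$profiles$sample_id, after$profiles$sample_id))
  pre <- permanova(dissimilarity_matrix(before, "bray_curtis"),
                   before$samples$study_id, n_permutations, seed = seed)
  post <- permanova(dissimilarity_matrix(after, "bray_curtis"),
                    after$samples$study_id, n_permutations, seed = seed)
  reduction <- if (pre$r_squared <= 0) NA_real_ else {
    100 * (pre$r_squared - post$r_squared) / pre$r_squared
  }
  list(reduction_pct = reduction, r2_before = pre$r_squared,
       r2_after = post$r_squared, permanova_before = pre,
       permanova_after = post)
}
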