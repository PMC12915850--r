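#' Shannon diversity (natural log)
#'
#' `H = -sum(p_i * log(p_i))` over the normalized abundances, with
#' `0 * log(0)` taken as 0.
#'
#' @param abundances Nonnegative abundance vector (any scale; normalized
#'   internally).
#' @return Shannon entropy in nats.
#' @examples
#' shannon(rep(1, 4))  # log(4)
#' @export
shannon <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be nonnegative", call. = FALSE)
  tot <- sum(abundances)
  if (tot == 0) stop("all-zero abundance vector", call. = FALSE)
  p <- abundances / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-sample alpha diversity
#'
#' @param ds An [mgba_dataset()].
#' @return A tibble with `sample_id`, `richness` (taxa with nonzero
#'   abundance) and `shannon`.
#' @export
alpha_diversity <- function(ds) {
  m <- taxon_matrix(ds)
  tibble::tibble(
    sample_id = rownames(m),
    richness = rowSums(m > 0),
    shannon = apply(m, 1, shannon)
  )
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `BC = sum(|x - y|) / sum(x + y)`.
#'
#' @param x,y Nonnegative abundance vectors of equal length.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("abundances must be nonnegative", call. = FALSE)
  den <- sum(x + y)
  if (den == 0) stop("both vectors are all zero", call. = FALSE)
  sum(abs(x - y)) / den
}

#' Jaccard dissimilarity between two abundance vectors
#'
#' One minus the Jaccard index of the presence sets, where presence means
#' abundance strictly above `presence_threshold`.
#'
#' @inheritParams bray_curtis
#' @param presence_threshold Presence call threshold (default 0: any
#'   positive abundance counts, appropriate after QC zeroing).
#' @return Dissimilarity in `[0, 1]`.
#' @export
jaccard <- function(x, y, presence_threshold = 0) {
  stopifnot(length(x) == length(y))
  a <- x > presence_threshold
  b <- y > presence_threshold
  u <- sum(a | b)
  if (u == 0) stop("both presence sets are empty", call. = FALSE)
  1 - sum(a & b) / u
}

#' Pairwise dissimilarity matrix
#'
#' @param ds An [mgba_dataset()] or a samples-by-taxa numeric matrix with
#'   row names.
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @param presence_threshold Presence threshold for the Jaccard metric.
#' @return An object of class `mgba_dist`: list with `sample_ids`, the
#'   symmetric `matrix`, and `metric`.
#' @export
dissimilarity_matrix <- function(ds, metric = c("bray_curtis", "jaccard"),
                                 presence_threshold = 0) {
  metric <- match.arg(metric)
  m <- if (inherits(ds, "mgba_dataset")) taxon_matrix(ds) else as.matrix(ds)
  if (is.null(rownames(m))) rownames(m) <- paste0("sample", seq_len(nrow(m)))
  if (metric == "bray_curtis") {
    num <- as.matrix(stats::dist(m, method = "manhattan"))
    s <- rowSums(m)
    den <- outer(s, s, "+")
    d <- num / den
  } else {
    p <- (m > presence_threshold) * 1
    inter <- tcrossprod(p)
    r <- rowSums(p)
    union <- outer(r, r, "+") - inter
    d <- 1 - inter / union
    d[union == 0] <- 0
  }
  diag(d) <- 0
  structure(list(sample_ids = rownames(m), matrix = d, metric = metric),
            class = "mgba_dist")
}

#' @export
print.mgba_dist <- function(x, ...) {
  cat(sprintf("<mgba_dist> %s, %d samples\n", x$metric, length(x$sample_ids)))
  invisible(x)
}

as_dist_matrix <- function(d) {
  if (inherits(d, "mgba_dist")) d$matrix else as.matrix(d)
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Double-centers `-D^2 / 2` and eigendecomposes it. Coordinates are
#' returned for the positive eigenvalues only; negative eigenvalues (which
#' arise for non-Euclidean dissimilarities such as Bray-Curtis) are reported
#' rather than silently dropped.
#'
#' @param d An `mgba_dist` (or square symmetric matrix).
#' @param ndim Number of axes to keep (default: all positive eigenvalues).
#' @return An object of class `mgba_pcoa`: `coordinates` (tibble with
#'   `sample_id` and `Axis.1 ...`), `eigenvalues` (all of them, sorted
#'   decreasing), and `variance_explained` relative to the sum of positive
#'   eigenvalues.
#' @export
pcoa <- function(d, ndim = NULL) {
  m <- as_dist_matrix(d)
  n <- nrow(m)
  if (n < 3) stop("need at least 3 samples for ordination", call. = FALSE)
  ids <- if (inherits(d, "mgba_dist")) d$sample_ids else
    (rownames(m) %||% paste0("sample", seq_len(n)))
  a <- -0.5 * m^2
  centered <- t(t(a - rowMeans(a)) - colMeans(a)) + mean(a)
  e <- eigen(centered, symmetric = TRUE)
  pos <- e$values > sqrt(.Machine$double.eps) * max(abs(e$values))
  k <- sum(pos)
  if (!is.null(ndim)) k <- min(k, ndim)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
  colnames(coords) <- paste0("Axis.", seq_len(k))
  structure(list(
    coordinates = dplyr::bind_cols(tibble::tibble(sample_id = ids),
                                   tibble::as_tibble(coords)),
    eigenvalues = e$values,
    variance_explained = e$values[seq_len(k)] / sum(e$values[e$values > 0])
  ), class = "mgba_pcoa")
}

#' One-factor PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance. With `N` samples in `a`
#' groups: `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`,
#' `SS_between = SS_total - SS_within`, `R2 = SS_between / SS_total`, and
#' `pseudo-F = (SS_between / (a-1)) / (SS_within / (N-a))`. The p-value is
#' the add-one permutation tail probability
#' `(1 + #{F_perm >= F_obs}) / (1 + n_permutations)`, so it can never be
#' reported as zero.
#'
#' @param d An `mgba_dist` (or square symmetric matrix).
#' @param groups Group labels, one per sample (at least two groups, each
#'   with at least two samples).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Optional seed for the permutation stream.
#' @param strata Optional blocking factor: permutations shuffle labels only
#'   within each stratum.
#' @return An object of class `permanova_result` with `r_squared`,
#'   `pseudo_f`, `p_value`, `n_permutations`, `df_between`, `df_within`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = NULL,
                      strata = NULL) {
  m <- as_dist_matrix(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2)) stop("every group needs at least 2 samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d2 <- m^2
  n <- nrow(m)
  a <- length(tab)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within_for <- function(g) {
    s <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ss_within <- ss_within_for(groups)
  ss_between <- ss_total - ss_within
  f_obs <- (ss_between / (a - 1)) / (ss_within / (n - a))
  r2 <- ss_between / ss_total

  perm_labels <- function() {
    if (is.null(strata)) {
      sample(groups)
    } else {
      g <- groups
      for (s in unique(strata)) {
        idx <- which(strata == s)
        g[idx] <- g[idx][sample.int(length(idx))]
      }
      g
    }
  }
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    sw <- ss_within_for(perm_labels())
    f_b <- ((ss_total - sw) / (a - 1)) / (sw / (n - a))
    if (f_b >= f_obs) exceed <- exceed + 1L
  }
  structure(list(r_squared = r2, pseudo_f = f_obs,
                 p_value = (1 + exceed) / (1 + n_permutations),
                 n_permutations = n_permutations,
                 df_between = a - 1, df_within = n - a,
                 ss_between = ss_between, ss_within = ss_within,
                 ss_total = ss_total),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: R2 = %.4f, pseudo-F = %.3f (df %d, %d), p = %.4g (%d permutations)\n",
              x$r_squared, x$pseudo_f, x$df_between, x$df_within,
              x$p_value, x$n_permutations))
  invisible(x)
}

#' Compare within-group community dissimilarities between cases and controls
#'
#' Collects all within-case and all within-control pairwise dissimilarities
#' and compares the two sets with a two-sided Wilcoxon rank-sum test — a way
#' of asking whether the disease group's community structure is more
#' heterogeneous than the healthy group's.
#'
#' @param d An `mgba_dist` (or square symmetric matrix).
#' @param groups Two-level labels (e.g. case/control), one per sample; each
#'   level needs at least 3 samples.
#' @return A tibble with one row per group (`group`, `n_pairs`,
#'   `median_dissimilarity`) plus attributes; and elements `p_value` and
#'   `median_difference` (first level minus second) in the returned list of
#'   class `dispersion_test`.
#' @export
within_group_dissimilarity_test <- function(d, groups) {
  m <- as_dist_matrix(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  levs <- sort(unique(groups))
  if (length(levs) != 2) stop("need exactly 2 groups", call. = FALSE)
  if (any(table(groups) < 3)) stop("each group needs >= 3 samples", call. = FALSE)
  vals <- lapply(levs, function(lev) {
    idx <- which(groups == lev)
    sub <- m[idx, idx]
    sub[upper.tri(sub)]
  })
  names(vals) <- levs
  pooled <- unlist(vals)
  if (length(unique(pooled)) == 1) {
    p <- 1  # fully tied: degenerate test
  } else {
    p <- stats::wilcox.test(vals[[1]], vals[[2]], exact = FALSE)$p.value
  }
  structure(list(
    summary = tibble::tibble(
      group = levs,
      n_pairs = vapply(vals, length, integer(1)),
      median_dissimilarity = vapply(vals, stats::median, numeric(1))
    ),
    values = vals,
    median_difference = stats::median(vals[[1]]) - stats::median(vals[[2]]),
    p_value = p
  ), class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  print(x$summary)
  cat(sprintf("median difference = %.4f, rank-sum p = %.4g\n",
              x$median_difference, x$p_value))
  invisible(x)
}
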