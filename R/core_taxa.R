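#' Per-taxon prevalence among healthy samples
#'
#' Fraction of healthy (control) samples in which a taxon's abundance
#' reaches the detection cutoff, pooled across all healthy samples.
#'
#' @param ds An [mgba_dataset()] with at least one healthy sample.
#' @param abundance_cutoff Presence threshold (default the 1e-4 species
#'   detection limit).
#' @param per_cohort If `TRUE`, prevalence is computed per study and the
#'   reported value is the fraction of studies whose healthy-group
#'   prevalence is at least 50%.
#' @return A tibble with `taxon` and `prevalence`.
#' @export
healthy_prevalence <- function(ds, abundance_cutoff = 1e-4,
                               per_cohort = FALSE) {
  healthy <- !ds$samples$is_case
  if (!any(healthy)) stop("no healthy samples", call. = FALSE)
  m <- taxon_matrix(ds)[healthy, , drop = FALSE]
  if (!per_cohort) {
    prev <- colMeans(m >= abundance_cutoff)
  } else {
    study <- ds$samples$study_id[healthy]
    by_study <- vapply(unique(study), function(s) {
      colMeans(m[study == s, , drop = FALSE] >= abundance_cutoff)
    }, numeric(ncol(m)))
    prev <- rowMeans(by_study >= 0.5)
  }
  tibble::tibble(taxon = colnames(m), prevalence = unname(prev))
}

#' Taxa the health-index classifier relies on, in the healthy direction
#'
#' From a final model's feature importances, keeps the features with
#' importance above a rank cutoff whose direction points toward health:
#' increasing the feature's abundance (from its 10th to its 90th training
#' percentile, other features held at observed values) lowers the mean
#' predicted disease probability.
#'
#' @param final_model An `mgba_final_model`.
#' @param ds The training [mgba_dataset()] (used for the perturbation
#'   reference distribution).
#' @param top_fraction Keep the top fraction of nonzero-importance features
#'   by importance (default 1: all nonzero).
#' @return A tibble with `taxon`, `importance`, `direction`
#'   (`"health"`/`"disease"`/`"flat"`) and `selected`.
#' @export
index_discriminative_set <- function(final_model, ds, top_fraction = 1) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  imp <- feature_importance(final_model$model)
  m <- taxon_matrix(ds)
  missing_feats <- setdiff(final_model$features, colnames(m))
  if (length(missing_feats) > 0) {
    m <- cbind(m, matrix(0, nrow(m), length(missing_feats),
                         dimnames = list(rownames(m), missing_feats)))
  }
  direction <- vapply(imp$taxon, function(tx) {
    if (imp$importance[imp$taxon == tx] == 0) return("flat")
    lo <- stats::quantile(m[, tx], 0.1, names = FALSE)
    hi <- stats::quantile(m[, tx], 0.9, names = FALSE)
    if (hi <= lo) return("flat")
    m_lo <- m; m_lo[, tx] <- lo
    m_hi <- m; m_hi[, tx] <- hi
    dp <- mean(predict_prob(final_model$model, m_hi)) -
      mean(predict_prob(final_model$model, m_lo))
    if (dp < 0) "health" else if (dp > 0) "disease" else "flat"
  }, character(1))
  nonzero <- imp$importance > 0
  cut <- if (any(nonzero)) {
    stats::quantile(imp$importance[nonzero], 1 - top_fraction, names = FALSE)
  } else Inf
  tibble::tibble(
    taxon = imp$taxon, importance = imp$importance, direction = direction,
    selected = nonzero & imp$importance >= cut & direction == "health"
  )
}

#' Tri-criteria consensus of core health-associated taxa
#'
#' Intersects three independent lines of evidence: taxa consistently
#' health-enriched in the pooled differential analysis, taxa the health
#' index's classifier relies on in the healthy direction, and taxa
#' prevalent in at least half of healthy individuals. The consensus is the
#' set carrying all three flags, ordered by classifier importance.
#'
#' @param directions Output of [classify_directions()].
#' @param discriminative Output of [index_discriminative_set()].
#' @param prevalence Output of [healthy_prevalence()].
#' @param prevalence_cutoff Minimum healthy prevalence (default 0.5).
#' @return A list of class `core_taxa_report`: `report` (per-taxon tibble
#'   with the three logical flags, supporting numbers and `consensus`) and
#'   `consensus` (character vector, importance-ordered).
#' @export
core_taxa_consensus <- function(directions, discriminative, prevalence,
                                prevalence_cutoff = 0.5) {
  universe <- union(union(directions$taxon, discriminative$taxon),
                    prevalence$taxon)
  if (length(universe) == 0) stop("empty taxon universe", call. = FALSE)
  report <- tibble::tibble(taxon = sort(universe)) |>
    dplyr::left_join(
      dplyr::transmute(directions, .data$taxon,
                       health_enriched = .data$category == "consistent_health"),
      by = "taxon") |>
    dplyr::left_join(
      dplyr::transmute(discriminative, .data$taxon,
                       index_discriminative = .data$selected,
                       importance = .data$importance),
      by = "taxon") |>
    dplyr::left_join(prevalence, by = "taxon") |>
    dplyr::mutate(
      health_enriched = !is.na(.data$health_enriched) & .data$health_enriched,
      index_discriminative = !is.na(.data$index_discriminative) &
        .data$index_discriminative,
      importance = ifelse(is.na(.data$importance), 0, .data$importance),
      prevalence = ifelse(is.na(.data$prevalence), 0, .data$prevalence),
      prevalent_in_health = .data$prevalence >= prevalence_cutoff,
      consensus = .data$health_enriched & .data$index_discriminative &
        .data$prevalent_in_health
    ) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$taxon)
  structure(list(report = report,
                 consensus = report$taxon[report$consensus]),
            class = "core_taxa_report")
}

#' @export
print.core_taxa_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("<core_taxa_report> %d taxa: %d health-enriched, %d index-discriminative, %d prevalent; consensus = %d\n",
              nrow(r), sum(r$health_enriched), sum(r$index_discriminative),
              sum(r$prevalent_in_health), length(x$consensus)))
  if (length(x$consensus) > 0) {
    cat("  ", paste(x$consensus, collapse = ", "), "\n")
  }
  invisible(x)
}
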