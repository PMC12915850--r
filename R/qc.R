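#' Analysis configuration
#'
#' Thresholds and cross-validation settings shared across the pipeline.
#' Defaults are the conventional values for multi-cohort shotgun-metagenomic
#' meta-analysis: samples need at least 10 million reads and at most 30%
#' unclassified sequence; participants with BMI above 30 kg/m2 are excluded
#' to control for obesity; studies keeping fewer than 10 samples are dropped
#' whole; species profiles are refined at a 1e-4 relative-abundance cutoff
#' with a 1% occurrence threshold; discoveries are called at FDR-adjusted
#' p < 0.1; and model evaluation uses 10-times-repeated 5-fold nested CV.
#'
#' @param min_read_count Minimum per-sample read count.
#' @param max_unclassified Maximum unclassified fraction.
#' @param max_bmi Maximum BMI (kg/m2); samples with missing BMI are kept.
#' @param min_study_n Minimum samples a study must retain after the
#'   per-sample filters.
#' @param abundance_cutoff Relative-abundance detection limit.
#' @param occurrence_cutoff Minimum fraction of samples in which a taxon
#'   must reach `abundance_cutoff` to be retained.
#' @param occurrence_on_nonzero If `TRUE`, occurrence counts any nonzero
#'   value as present instead of requiring `abundance_cutoff`.
#' @param renormalize Re-close each sample's composition after species
#'   filtering (off by default: absolute fractions stay comparable across
#'   filter settings).
#' @param fdr_threshold BH-adjusted significance threshold.
#' @param prevalence_cutoff Healthy-prevalence threshold for core taxa.
#' @param outer_folds,inner_folds,repeats Nested-CV design.
#' @param search_budget Hyperparameter-search evaluations per tuning run.
#' @param pseudocount Added before log10 transforms (half the abundance
#'   cutoff).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(min_read_count = 1e7,
                            max_unclassified = 0.30,
                            max_bmi = 30,
                            min_study_n = 10,
                            abundance_cutoff = 1e-4,
                            occurrence_cutoff = 0.01,
                            occurrence_on_nonzero = FALSE,
                            renormalize = FALSE,
                            fdr_threshold = 0.1,
                            prevalence_cutoff = 0.5,
                            outer_folds = 5,
                            inner_folds = 5,
                            repeats = 10,
                            search_budget = 30,
                            pseudocount = 5e-5) {
  cfg <- as.list(environment())
  stopifnot(min_read_count >= 0, max_unclassified >= 0, max_unclassified <= 1,
            max_bmi > 0, min_study_n >= 0,
            abundance_cutoff >= 0, occurrence_cutoff >= 0,
            occurrence_cutoff <= 1, fdr_threshold > 0, fdr_threshold <= 1,
            prevalence_cutoff >= 0, prevalence_cutoff <= 1,
            outer_folds >= 2, inner_folds >= 2, repeats >= 1,
            search_budget >= 1, pseudocount > 0)
  structure(cfg, class = "analysis_config")
}

#' Filter samples and studies
#'
#' Applies the per-sample quality filters — read count below
#' `min_read_count`, unclassified fraction above `max_unclassified`, BMI
#' above `max_bmi` — and then removes whole studies left with fewer than
#' `min_study_n` samples. Missing BMI (or any missing optional field) never
#' excludes a sample here; analyses requiring a field drop its missing
#' records themselves. Each excluded sample is audited with the first rule
#' that caught it (rules applied in the order read count, unclassified
#' fraction, BMI, study size).
#'
#' @param ds An [mgba_dataset()].
#' @param cfg An [analysis_config()].
#' @return A list of class `qc_result`: `dataset` (the filtered
#'   `mgba_dataset`), `audit` (tibble of `sample_id`, `study_id`, `reason`
#'   with reason `"none"` for survivors), `n_before`, `n_after`.
#' @export
filter_samples <- function(ds, cfg = analysis_config()) {
  md <- ds$samples
  reason <- rep("none", nrow(md))
  has <- function(col) if (col %in% names(md)) md[[col]] else rep(NA_real_, nrow(md))
  rc <- has("read_count"); uf <- has("unclassified_fraction"); bmi <- has("bmi")
  fail_reads <- !is.na(rc) & rc < cfg$min_read_count
  fail_unclass <- !is.na(uf) & uf > cfg$max_unclassified
  fail_bmi <- !is.na(bmi) & bmi > cfg$max_bmi
  reason[reason == "none" & fail_reads] <- "low_reads"
  reason[reason == "none" & fail_unclass] <- "high_unclassified"
  reason[reason == "none" & fail_bmi] <- "high_bmi"
  keep <- reason == "none"
  study_n <- table(md$study_id[keep])
  small <- names(study_n)[study_n < cfg$min_study_n]
  small <- union(small, setdiff(unique(md$study_id), names(study_n)))
  reason[keep & md$study_id %in% small] <- "small_study"
  keep <- reason == "none"
  if (!any(keep)) stop("all samples excluded by QC filters", call. = FALSE)
  audit <- tibble::tibble(sample_id = md$sample_id, study_id = md$study_id,
                          reason = reason)
  structure(list(dataset = subset_samples(ds, keep), audit = audit,
                 n_before = nrow(md), n_after = sum(keep)),
            class = "qc_result")
}

#' Filter species
#'
#' Refines the species profile: a taxon is retained iff the fraction of
#' samples in which its abundance reaches `abundance_cutoff` is at least
#' `occurrence_cutoff`. In retained taxa, sub-detection values (below
#' `abundance_cutoff`) are zeroed. Compositions are not re-closed unless
#' `cfg$renormalize` is set.
#'
#' @inheritParams filter_samples
#' @return A list of class `qc_result`: `dataset`, `audit` (tibble of
#'   `taxon`, `occurrence`, `reason`), `n_before`, `n_after` (taxon counts).
#' @export
filter_species <- function(ds, cfg = analysis_config()) {
  m <- taxon_matrix(ds)
  present <- if (cfg$occurrence_on_nonzero) m > 0 else m >= cfg$abundance_cutoff
  occurrence <- unname(colMeans(present))
  keep <- occurrence >= cfg$occurrence_cutoff
  if (!any(keep)) stop("all taxa removed by species filter", call. = FALSE)
  audit <- tibble::tibble(
    taxon = colnames(m), occurrence = occurrence,
    reason = ifelse(keep, "none", "low_abundance_and_occurrence")
  )
  m2 <- m[, keep, drop = FALSE]
  m2[m2 < cfg$abundance_cutoff] <- 0
  if (cfg$renormalize) {
    uf <- if ("unclassified_fraction" %in% names(ds$samples)) {
      ds$samples$unclassified_fraction
    } else 0
    tot <- rowSums(m2)
    nz <- tot > 0
    m2[nz, ] <- m2[nz, , drop = FALSE] / tot[nz] * (1 - uf)[nz]
  }
  structure(list(dataset = set_taxon_matrix(ds, m2), audit = audit,
                 n_before = ncol(m), n_after = sum(keep)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  unit <- if ("taxon" %in% names(x$audit)) "taxa" else "samples"
  cat(sprintf("<qc_result> %d -> %d %s\n", x$n_before, x$n_after, unit))
  excl <- dplyr::count(dplyr::filter(x$audit, .data$reason != "none"),
                       .data$reason)
  if (nrow(excl) > 0) {
    for (i in seq_len(nrow(excl))) {
      cat(sprintf("  %s: %d\n", excl$reason[i], excl$n[i]))
    }
  }
  invisible(x)
}
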