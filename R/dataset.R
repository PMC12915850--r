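#' Construct a multi-study microbiome dataset
#'
#' Bundles a samples-by-taxa relative-abundance table with per-sample
#' metadata (and, for simulated data, the planted ground truth) into the
#' container every analysis stage of the package consumes.
#'
#' @param profiles A tibble whose first column is `sample_id` and whose
#'   remaining columns are species-level taxa holding relative abundances as
#'   fractions in `[0, 1]`. Per-sample fractions may sum to less than 1: the
#'   remainder is the unclassified portion of the community.
#' @param samples A tibble of per-sample metadata with at least `sample_id`,
#'   `study_id`, `disease` and `is_case`. Optional columns `age`, `sex`,
#'   `bmi`, `read_count` and `unclassified_fraction` are used by the QC
#'   filters; any further numeric columns are treated as phenotype scores.
#' @param truth Optional planted ground truth as produced by
#'   [simulate_dataset()]; `NULL` for real data.
#' @param healthy_label The `disease` value marking controls. Default
#'   `"healthy"`.
#'
#' @return An object of class `mgba_dataset`: a list with elements
#'   `profiles`, `samples`, `truth` and `healthy_label`.
#'
#' @details Invariants enforced at construction: abundances are nonnegative,
#'   each sample's taxon fractions sum to at most `1 + 1e-6`, sample and
#'   taxon identifiers are unique, the two tables agree in sample content and
#'   order, and `is_case` is `FALSE` exactly for samples labelled with
#'   `healthy_label`.
#'
#' @examples
#' ds <- simulate_dataset(sim_params(n_studies = 2, n_cases = 5,
#'                                   n_controls = 5, n_taxa = 20, seed = 1))
#' ds
#' @export
mgba_dataset <- function(profiles, samples, truth = NULL,
                         healthy_label = "healthy") {
  profiles <- tibble::as_tibble(profiles)
  samples <- tibble::as_tibble(samples)
  if (!identical(names(profiles)[1], "sample_id")) {
    stop("`profiles` must have `sample_id` as its first column", call. = FALSE)
  }
  required <- c("sample_id", "study_id", "disease", "is_case")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    stop("`samples` is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(profiles$sample_id)) {
    stop("duplicate sample ids in `profiles`", call. = FALSE)
  }
  taxa <- setdiff(names(profiles), "sample_id")
  if (length(taxa) == 0) stop("`profiles` contains no taxa", call. = FALSE)
  if (anyDuplicated(taxa)) stop("duplicate taxon names", call. = FALSE)
  m <- as.matrix(profiles[taxa])
  if (!is.numeric(m)) stop("abundances must be numeric", call. = FALSE)
  if (anyNA(m)) stop("abundances must not be missing", call. = FALSE)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance for sample '%s', taxon '%s'",
                 profiles$sample_id[bad[1]], taxa[bad[2]]), call. = FALSE)
  }
  sums <- rowSums(m)
  if (any(sums > 1 + 1e-6)) {
    stop(sprintf("sample '%s' has taxon fractions summing to %.6f > 1",
                 profiles$sample_id[which.max(sums)], max(sums)),
         call. = FALSE)
  }
  if (!identical(profiles$sample_id, samples$sample_id)) {
    stop("`profiles` and `samples` must list the same sample ids in the ",
         "same order; use align_dataset() to harmonize them", call. = FALSE)
  }
  healthy <- samples$disease == healthy_label
  if (any(samples$is_case == healthy, na.rm = TRUE)) {
    stop("`is_case` must be FALSE exactly for samples with disease == '",
         healthy_label, "'", call. = FALSE)
  }
  structure(
    list(profiles = profiles, samples = samples, truth = truth,
         healthy_label = healthy_label),
    class = "mgba_dataset"
  )
}

#' @export
print.mgba_dataset <- function(x, ...) {
  n <- nrow(x$profiles)
  p <- length(taxa_names(x))
  studies <- unique(x$samples$study_id)
  cat(sprintf("<mgba_dataset> %d samples x %d taxa, %d stud%s (%s)\n",
              n, p, length(studies), if (length(studies) == 1) "y" else "ies",
              paste(utils::head(studies, 5), collapse = ", ")))
  cat(sprintf("  cases: %d, controls: %d; diseases: %s\n",
              sum(x$samples$is_case), sum(!x$samples$is_case),
              paste(setdiff(unique(x$samples$disease), x$healthy_label),
                    collapse = ", ")))
  if (!is.null(x$truth)) {
    cat(sprintf("  planted truth: %d disease taxa (%d protective)\n",
                length(x$truth$disease_taxa), length(x$truth$protective_taxa)))
  }
  invisible(x)
}

#' Taxon names of a dataset
#' @param ds An `mgba_dataset`.
#' @return Character vector of taxon identifiers.
#' @export
taxa_names <- function(ds) setdiff(names(ds$profiles), "sample_id")

#' Abundance matrix of a dataset
#'
#' @param ds An `mgba_dataset`.
#' @return A numeric matrix (samples x taxa) of relative-abundance fractions
#'   with sample ids as row names.
#' @export
taxon_matrix <- function(ds) {
  taxa <- taxa_names(ds)
  m <- as.matrix(ds$profiles[taxa])
  rownames(m) <- ds$profiles$sample_id
  m
}

## Replace the abundance matrix of a dataset, keeping metadata and truth.
set_taxon_matrix <- function(ds, m) {
  stopifnot(nrow(m) == nrow(ds$profiles))
  prof <- dplyr::bind_cols(
    tibble::tibble(sample_id = ds$profiles$sample_id),
    tibble::as_tibble(m)
  )
  ds$profiles <- prof
  ds
}

#' Align a profile table with a metadata table
#'
#' Keeps the intersection of sample ids, harmonizes their order, and reports
#' how many ids were dropped from each side.
#'
#' @param profiles A tibble as accepted by [mgba_dataset()].
#' @param samples A metadata tibble as accepted by [mgba_dataset()].
#' @inheritParams mgba_dataset
#' @param quiet Suppress the message reporting dropped ids.
#' @return An `mgba_dataset` restricted to the shared samples. The counts of
#'   ids dropped from each table are attached as attribute `"dropped"`.
#' @export
align_dataset <- function(profiles, samples, truth = NULL,
                          healthy_label = "healthy", quiet = FALSE) {
  profiles <- tibble::as_tibble(profiles)
  samples <- tibble::as_tibble(samples)
  shared <- intersect(profiles$sample_id, samples$sample_id)
  if (length(shared) == 0) {
    stop("no sample ids shared between profiles and metadata", call. = FALSE)
  }
  dropped <- c(profiles = nrow(profiles) - length(shared),
               samples = nrow(samples) - length(shared))
  if (!quiet && sum(dropped) > 0) {
    message(sprintf("align_dataset: dropped %d profile-only and %d metadata-only samples",
                    dropped[["profiles"]], dropped[["samples"]]))
  }
  profiles <- profiles[match(shared, profiles$sample_id), ]
  samples <- samples[match(shared, samples$sample_id), ]
  ds <- mgba_dataset(profiles, samples, truth = truth,
                     healthy_label = healthy_label)
  attr(ds, "dropped") <- dropped
  ds
}

## Subset a dataset by a logical or integer sample index.
subset_samples <- function(ds, idx) {
  ds$profiles <- ds$profiles[idx, , drop = FALSE]
  ds$samples <- ds$samples[idx, , drop = FALSE]
  ds
}

## Subset a dataset to the given taxa (character vector).
subset_taxa <- function(ds, taxa) {
  ds$profiles <- ds$profiles[c("sample_id", taxa)]
  ds
}

## 0/1 outcome vector: 1 = case.
case_labels <- function(ds) as.integer(ds$samples$is_case)
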