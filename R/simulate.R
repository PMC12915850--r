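#' Parameters for the synthetic multi-cohort generator
#'
#' Collects the knobs of the generative model used by [simulate_dataset()].
#' Defaults describe a moderate multi-study case-control design: three
#' cohorts of 50 cases and 50 controls, 200 species, 10 disease-affected
#' species at a 1 log2-unit fold change (half of them "protective":
#' health-enriched and highly prevalent), and study-level multiplicative
#' batch bias with standard deviation 0.5 on the log2 scale.
#'
#' @param n_studies Number of studies (cohorts).
#' @param n_cases,n_controls Cases and controls per study (each must be
#'   at least 1 — a matched case-control design is assumed).
#' @param n_taxa Number of species.
#' @param n_disease_taxa Number of species carrying a planted disease effect.
#' @param n_protective_taxa How many of the disease taxa are planted as
#'   protective: case-depleted (negative fold change), near-universal in
#'   controls (zero-inflation capped at 0.05) and with an elevated baseline.
#' @param effect_size Planted |log2 fold change| of disease taxa.
#' @param batch_sd Standard deviation of the per-study per-taxon log2 bias.
#' @param noise_sd Residual log2 noise of the latent abundances.
#' @param base_log_mean_sd Spread of per-taxon baseline log2 means.
#' @param zero_inflation Length-2 range of per-taxon structural-absence
#'   probabilities (drawn uniformly).
#' @param read_count_meanlog,read_count_sdlog Log-normal read-count model.
#' @param low_read_fraction Fraction of samples given a read count below
#'   10 million, to exercise the QC read-depth filter.
#' @param unclassified_shape1,unclassified_shape2 Beta model of the
#'   unclassified fraction (mean 0.12 by default, occasionally above 0.30).
#' @param high_bmi_fraction Fraction of samples given BMI above 30.
#' @param phenotype_effect Shift of the simulated `severity` phenotype in
#'   cases, in its own standard-deviation units.
#' @param disease Disease label given to cases.
#' @param seed Integer seed fixing the full output.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_studies = 3, n_cases = 50, n_controls = 50,
                       n_taxa = 200, n_disease_taxa = 10,
                       n_protective_taxa = min(5, n_disease_taxa),
                       effect_size = 1, batch_sd = 0.5, noise_sd = 1,
                       base_log_mean_sd = 2,
                       zero_inflation = c(0, 0.7),
                       read_count_meanlog = log(3e7), read_count_sdlog = 0.4,
                       low_read_fraction = 0,
                       unclassified_shape1 = 3, unclassified_shape2 = 22,
                       high_bmi_fraction = 0,
                       phenotype_effect = 1,
                       disease = "PD", seed = 1) {
  p <- as.list(environment())
  stopifnot(n_studies >= 1, n_cases >= 1, n_controls >= 1, n_taxa >= 2,
            n_disease_taxa >= 0, n_disease_taxa <= n_taxa,
            n_protective_taxa <= n_disease_taxa,
            is.finite(effect_size), batch_sd >= 0, noise_sd >= 0,
            length(zero_inflation) == 2, all(zero_inflation >= 0),
            all(zero_inflation <= 1))
  structure(p, class = "sim_params")
}

## Deterministic substream seed (kept below 2^31).
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + index * 9973) %% 2147483647L)
}

## Draw the global planted truth (taxon baselines, disease effects,
## zero-inflation) under the params seed.
draw_truth <- function(params) {
  set.seed(substream_seed(params$seed, 0))
  taxa <- sprintf("s__Taxon_%03d", seq_len(params$n_taxa))
  base_log_mean <- stats::rnorm(params$n_taxa, 0, params$base_log_mean_sd)
  names(base_log_mean) <- taxa
  zi <- stats::runif(params$n_taxa, params$zero_inflation[1],
                     params$zero_inflation[2])
  names(zi) <- taxa
  disease_idx <- sample.int(params$n_taxa, params$n_disease_taxa)
  disease_taxa <- numeric(0)
  protective <- character(0)
  if (params$n_disease_taxa > 0) {
    prot_idx <- disease_idx[seq_len(params$n_protective_taxa)]
    other_idx <- setdiff(disease_idx, prot_idx)
    sign_other <- rep_len(c(1, -1), length(other_idx))
    disease_taxa <- c(rep(-params$effect_size, length(prot_idx)),
                      sign_other * params$effect_size)
    names(disease_taxa) <- taxa[c(prot_idx, other_idx)]
    protective <- taxa[prot_idx]
    # protective taxa: near-universal in health, elevated baseline
    zi[prot_idx] <- pmin(zi[prot_idx], 0.05)
    base_log_mean[prot_idx] <- abs(base_log_mean[prot_idx]) + 1
  }
  list(disease_taxa = disease_taxa, protective_taxa = protective,
       base_log_mean = base_log_mean, base_log_sd = params$noise_sd,
       zero_inflation = zi, taxa = taxa)
}

## Simulate the samples of one study given truth and a study-specific bias
## vector; returns list(profiles matrix, samples tibble).
simulate_study <- function(params, truth, study_id, bias, seed) {
  set.seed(seed)
  taxa <- truth$taxa
  n <- params$n_cases + params$n_controls
  is_case <- c(rep(TRUE, params$n_cases), rep(FALSE, params$n_controls))
  lfc <- stats::setNames(numeric(length(taxa)), taxa)
  lfc[names(truth$disease_taxa)] <- truth$disease_taxa
  mu <- matrix(truth$base_log_mean + bias, nrow = n, ncol = length(taxa),
               byrow = TRUE)
  mu <- mu + outer(as.numeric(is_case), lfc)
  latent <- mu + matrix(stats::rnorm(n * length(taxa), 0, params$noise_sd),
                        nrow = n)
  present <- matrix(stats::runif(n * length(taxa)), nrow = n) >=
    matrix(truth$zero_inflation, nrow = n, ncol = length(taxa), byrow = TRUE)
  x <- ifelse(present, 2^latent, 0)
  # guard: a sample must contain at least one taxon
  empty <- rowSums(x) == 0
  if (any(empty)) {
    top <- max.col(latent[empty, , drop = FALSE])
    x[cbind(which(empty), top)] <- 2^latent[cbind(which(empty), top)]
  }
  uf <- stats::rbeta(n, params$unclassified_shape1, params$unclassified_shape2)
  rel <- x / rowSums(x) * (1 - uf)
  colnames(rel) <- taxa

  read_count <- round(stats::rlnorm(n, params$read_count_meanlog,
                                    params$read_count_sdlog))
  n_low <- round(params$low_read_fraction * n)
  if (n_low > 0) {
    low_idx <- sample.int(n, n_low)
    read_count[low_idx] <- round(stats::runif(n_low, 1e6, 9.99e6))
  }
  read_count <- pmax(read_count, 1)
  bmi <- stats::rnorm(n, 24, 3)
  n_hi <- round(params$high_bmi_fraction * n)
  if (n_hi > 0) {
    hi_idx <- sample.int(n, n_hi)
    bmi[hi_idx] <- stats::runif(n_hi, 30.5, 36)
  }
  samples <- tibble::tibble(
    sample_id = sprintf("%s_%03d", study_id, seq_len(n)),
    study_id = study_id,
    disease = ifelse(is_case, params$disease, "healthy"),
    is_case = is_case,
    age = round(pmin(pmax(stats::rnorm(n, 45, 12), 18), 85), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    bmi = round(bmi, 1),
    read_count = read_count,
    unclassified_fraction = uf,
    severity = round(params$phenotype_effect * as.numeric(is_case) +
                       stats::rnorm(n), 3)
  )
  rownames(rel) <- samples$sample_id
  list(profiles = rel, samples = samples)
}

#' Simulate a multi-study case-control microbiome dataset
#'
#' Generates compositional species profiles from a zero-inflated log-normal
#' model with per-study multiplicative batch bias and planted multiplicative
#' disease effects, plus realistic per-sample metadata (age, sex, BMI, read
#' count, unclassified fraction, and a `severity` phenotype). The planted
#' ground truth is recorded on the returned dataset so downstream stages can
#' be validated against it.
#'
#' @details Per sample, the generative model draws a latent log2 abundance
#'   for each taxon as `base + study bias + is_case * log2FC + noise`,
#'   applies a per-taxon structural-absence (zero-inflation) mask,
#'   exponentiates, and closes the composition: fractions are scaled to sum
#'   to `1 - unclassified_fraction`. One global seed expands into per-study
#'   substreams, so adding a study never perturbs existing ones.
#'
#' @param params A [sim_params()] object.
#' @return An [mgba_dataset()] with the planted truth in `$truth`.
#' @examples
#' ds <- simulate_dataset(sim_params(n_studies = 2, n_cases = 10,
#'                                   n_controls = 10, n_taxa = 30, seed = 7))
#' ds
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  truth <- draw_truth(params)
  build_cohorts(params, truth, prefix = "study")
}

#' Simulate an external validation cohort from an existing planted truth
#'
#' Draws new studies carrying the same taxon baselines and disease effects
#' as a previously simulated dataset, but with fresh study-level batch
#' biases — emulating an unseen platform or population for external
#' validation.
#'
#' @param params A [sim_params()] object governing the new studies (counts,
#'   batch_sd, seed, ...). Taxon-level structure is taken from `truth`, so
#'   `n_taxa`/`n_disease_taxa` in `params` are ignored.
#' @param truth The `$truth` of a dataset produced by [simulate_dataset()].
#' @return An [mgba_dataset()] whose studies are prefixed `"ext"`.
#' @export
inject_external_cohort <- function(params, truth) {
  stopifnot(inherits(params, "sim_params"),
            is.list(truth), !is.null(truth$taxa))
  build_cohorts(params, truth, prefix = "ext")
}

build_cohorts <- function(params, truth, prefix) {
  studies <- vector("list", params$n_studies)
  batch_bias <- matrix(0, params$n_studies, length(truth$taxa),
                       dimnames = list(NULL, truth$taxa))
  for (s in seq_len(params$n_studies)) {
    study_id <- sprintf("%s%02d", prefix, s)
    set.seed(substream_seed(params$seed, 2L * s))
    bias <- stats::rnorm(length(truth$taxa), 0, params$batch_sd)
    batch_bias[s, ] <- bias
    studies[[s]] <- simulate_study(params, truth, study_id, bias,
                                   seed = substream_seed(params$seed, 2L * s + 1L))
  }
  rownames(batch_bias) <- sprintf("%s%02d", prefix, seq_len(params$n_studies))
  profiles <- do.call(rbind, lapply(studies, `[[`, "profiles"))
  samples <- dplyr::bind_rows(lapply(studies, `[[`, "samples"))
  truth$batch_bias <- batch_bias
  truth$params <- params
  prof <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(profiles)),
                           tibble::as_tibble(profiles))
  mgba_dataset(prof, samples, truth = truth)
}
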