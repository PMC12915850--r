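#' Configuration for an end-to-end pipeline run
#'
#' @param sim A [sim_params()] describing the synthetic input, or `NULL`
#'   when `profiles_path`/`metadata_path` point at real tables.
#' @param profiles_path,metadata_path TSV inputs (used when `sim` is
#'   `NULL`).
#' @param cfg An [analysis_config()].
#' @param spec A [model_spec()].
#' @param run_qc,run_batch_correction,run_ecology Stage switches.
#' @param cv `"loco"` (requires >= 3 cohorts) or `"nested"`.
#' @param repeats Nested-CV repeats when `cv = "nested"`.
#' @param n_permutations PERMANOVA permutations.
#' @param n_boot Bootstrap resamples for index-phenotype CIs.
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as TSV/JSON and listed in the manifest.
#' @param seed Top-level seed, expanded deterministically per stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_params(), profiles_path = NULL,
                            metadata_path = NULL, cfg = analysis_config(),
                            spec = model_spec("lasso_logistic",
                                              search_budget = 10),
                            run_qc = TRUE, run_batch_correction = TRUE,
                            run_ecology = TRUE,
                            cv = c("loco", "nested"), repeats = 10,
                            n_permutations = 999, n_boot = 1000,
                            out_dir = NULL, seed = 1) {
  cv <- match.arg(cv)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, QC, optional batch correction, community
#' ecology, per-cohort differential analysis with random-effects pooling,
#' classifier cross-validation (LOCO or nested), final-model fitting, the
#' health index with its evaluation, and the core-taxa consensus — each
#' stage seeded deterministically from the top-level seed. A failing stage
#' aborts with the stage name; results of completed stages are attached to
#' the error condition's `partial` field.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_run`: `manifest` (config snapshot,
#'   seeds, package version, per-stage output summary, file paths when
#'   `out_dir` was set) and `results` (per-stage objects).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  results <- list()
  stage_seeds <- list()
  stage <- function(name, expr) {
    stage_seeds[[name]] <<- substream_seed(config$seed,
                                           length(stage_seeds) + 300L)
    set.seed(stage_seeds[[name]])
    tryCatch(expr, error = function(e) {
      stop(structure(class = c("pipeline_error", "error", "condition"),
                     list(message = sprintf("stage '%s' failed: %s", name,
                                            conditionMessage(e)),
                          call = NULL, partial = results)))
    })
  }

  ds <- stage("input", {
    if (!is.null(config$sim)) {
      simulate_dataset(config$sim)
    } else {
      align_dataset(read_profile_table(config$profiles_path),
                    read_metadata(config$metadata_path), quiet = TRUE)
    }
  })
  results$input <- list(n_samples = nrow(ds$profiles),
                        n_taxa = length(taxa_names(ds)))

  if (config$run_qc) {
    qc_s <- stage("qc_samples", filter_samples(ds, config$cfg))
    qc_t <- stage("qc_species", filter_species(qc_s$dataset, config$cfg))
    ds <- qc_t$dataset
    results$qc <- list(samples = qc_s, species = qc_t)
  }

  if (config$run_ecology) {
    results$ecology <- stage("ecology", {
      d <- dissimilarity_matrix(ds, "bray_curtis")
      list(
        alpha = alpha_diversity(ds),
        disease_permanova = permanova(d, ifelse(ds$samples$is_case,
                                                "case", "control"),
                                      config$n_permutations),
        batch_permanova = if (length(unique(ds$samples$study_id)) > 1) {
          permanova(d, ds$samples$study_id, config$n_permutations)
        },
        dispersion = within_group_dissimilarity_test(
          d, ifelse(ds$samples$is_case, "case", "control"))
      )
    })
  }

  results$differential <- stage("differential", {
    assoc <- associate_cohorts(ds, "abundance",
                               pseudocount = config$cfg$pseudocount)
    pooled <- pool_associations(assoc)
    list(associations = assoc, pooled = pooled,
         directions = classify_directions(pooled, config$cfg$fdr_threshold))
  })

  if (config$run_batch_correction &&
      length(unique(ds$samples$study_id)) > 1) {
    results$batch <- stage("batch_correction", {
      corr <- eb_batch_correct(ds, pseudocount = config$cfg$pseudocount)
      red <- batch_variance_reduction(ds, corr$dataset,
                                      config$n_permutations)
      list(correction = corr,
           reduction_pct = red$reduction_pct,
           r2_before = red$r2_before, r2_after = red$r2_after)
    })
    ds <- results$batch$correction$dataset
  }

  cv_report <- stage("cross_validation", {
    if (config$cv == "loco") {
      loco_cv(ds, config$spec, inner_folds = config$cfg$inner_folds,
              seed = substream_seed(config$seed, 401L))
    } else {
      nested_cv(ds, config$spec, repeats = config$repeats,
                outer_folds = config$cfg$outer_folds,
                inner_folds = config$cfg$inner_folds,
                seed = substream_seed(config$seed, 402L))
    }
  })
  results$cv_report <- cv_report

  results$final_model <- stage("final_model", {
    fm <- tune_final(ds, consensus_features(cv_report), config$spec,
                     seed = substream_seed(config$seed, 403L))
    fm$threshold <- youden_threshold(cv_report$oof$probability,
                                     cv_report$oof$label)
    fm
  })

  results$index <- stage("index", {
    idx <- index_for_dataset(
      ds,
      loco_report = if (config$cv == "loco") cv_report,
      final_model = results$final_model,
      threshold = results$final_model$threshold
    )
    pheno <- if ("severity" %in% names(ds$samples)) {
      ds$samples["severity"]
    }
    list(index = idx,
         evaluation = evaluate_index(idx$index, case_labels(ds),
                                     phenotypes = pheno,
                                     n_boot = config$n_boot,
                                     seed = substream_seed(config$seed, 404L)))
  })

  results$core_taxa <- stage("core_taxa", {
    core_taxa_consensus(
      results$differential$directions,
      index_discriminative_set(results$final_model, ds),
      healthy_prevalence(ds, config$cfg$abundance_cutoff),
      prevalence_cutoff = config$cfg$prevalence_cutoff
    )
  })

  manifest <- list(
    config = config,
    seed = config$seed,
    stage_seeds = stage_seeds,
    package_version = as.character(utils::packageVersion("microgba")),
    summary = list(
      n_samples = results$input$n_samples,
      n_taxa_post_qc = length(taxa_names(ds)),
      cv = config$cv,
      mean_cv_auroc = cv_report$mean_auroc,
      threshold = results$final_model$threshold,
      cliffs_delta = results$index$evaluation$group_test$cliffs_delta,
      n_core_taxa = length(results$core_taxa$consensus)
    )
  )
  if (!is.null(config$out_dir)) {
    manifest$outputs <- write_pipeline_outputs(config$out_dir, ds, results)
  }
  structure(list(manifest = manifest, results = results),
            class = "pipeline_run")
}

write_pipeline_outputs <- function(dir, ds, results) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    profiles = file.path(dir, "profiles_post_qc.tsv"),
    metadata = file.path(dir, "metadata_post_qc.tsv"),
    pooled = file.path(dir, "pooled_associations.tsv"),
    index = file.path(dir, "index.tsv"),
    core = file.path(dir, "core_taxa.tsv"),
    summary = file.path(dir, "summary.json")
  )
  write_profile_table(ds, paths[["profiles"]])
  write_metadata(ds, paths[["metadata"]])
  readr::write_tsv(results$differential$pooled, paths[["pooled"]],
                   progress = FALSE)
  readr::write_tsv(results$index$index, paths[["index"]], progress = FALSE)
  readr::write_tsv(results$core_taxa$report, paths[["core"]],
                   progress = FALSE)
  jsonlite::write_json(
    list(mean_cv_auroc = results$cv_report$mean_auroc,
         threshold = results$final_model$threshold,
         cliffs_delta = results$index$evaluation$group_test$cliffs_delta,
         core_taxa = results$core_taxa$consensus),
    paths[["summary"]], auto_unbox = TRUE, digits = NA)
  paths
}

#' @export
print.pipeline_run <- function(x, ...) {
  s <- x$manifest$summary
  cat("<pipeline_run>\n")
  cat(sprintf("  %d samples, %d taxa after QC; %s CV mean AUROC = %.3f\n",
              s$n_samples, s$n_taxa_post_qc, s$cv, s$mean_cv_auroc))
  cat(sprintf("  index threshold = %.3f, Cliff's delta = %.3f; %d core taxa\n",
              s$threshold, s$cliffs_delta, s$n_core_taxa))
  invisible(x)
}
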