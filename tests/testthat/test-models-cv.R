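test_that("auroc equals the pair-counting oracle and pROC", {
  set.seed(60)
  for (i in 1:1000) {
    n <- sample(6:25, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    expect_equal(auroc(s, y), auroc_oracle(s, y), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(61)
  for (i in 1:20) {
    y <- c(0, 1, rbinom(28, 1, 0.5))
    s <- runif(30)
    ref <- suppressMessages(pROC::auc(y, s, direction = "<"))
    expect_equal(auroc(s, y), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("feature importance follows the per-family rules", {
  set.seed(62)
  n <- 80
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.integer(x[, 1] + rnorm(n, 0, 0.4) > 0)
  spec <- model_spec("logistic")
  fit <- microgba:::fit_model(spec, x, y, list())
  imp <- feature_importance(fit)
  co <- stats::coef(fit$fit)[-1]
  expect_equal(imp$importance, unname(abs(co)))
  expect_true(all(imp$importance >= 0))
  expect_equal(sum(imp$normalized), 1, tolerance = 1e-9)
  expect_equal(imp$rule[1], "abs_coefficient")

  # a single informative feature dominates forest impurity importance
  set.seed(63)
  p <- 10
  x2 <- matrix(rnorm(n * p), n, p,
               dimnames = list(NULL, paste0("f", 1:p)))
  y2 <- as.integer(x2[, 4] > 0)
  rf <- microgba:::fit_model(model_spec("random_forest"), x2, y2,
                             list(mtry_frac = 0.5, min_node_size = 1,
                                  num_trees = 200))
  imp_rf <- feature_importance(rf)
  expect_equal(imp_rf$taxon[which.max(imp_rf$importance)], "f4")
  expect_equal(imp_rf$rule[1], "impurity_decrease")

  expect_error(feature_importance(list()), "not a fitted model")
})

test_that("outer folds are stratified and reports reproducible under a seed", {
  set.seed(64)
  y <- rep(c(0, 1), times = c(28, 22))
  for (i in 1:20) {
    fold <- microgba:::stratified_folds(y, 5)
    ratio <- tapply(y, fold, sum)
    expect_true(all(abs(ratio - mean(ratio)) <= 1))
  }

  ds <- simulate_dataset(sim_params(n_studies = 1, n_cases = 20,
                                    n_controls = 20, n_taxa = 40,
                                    effect_size = 1.5, seed = 65))
  spec <- model_spec("lasso_logistic", search_budget = 4)
  r1 <- nested_cv(ds, spec, repeats = 2, seed = 11)
  r2 <- nested_cv(ds, spec, repeats = 2, seed = 11)
  expect_identical(r1$fold_metrics, r2$fold_metrics)
  expect_identical(r1$selected_features, r2$selected_features)
  expect_identical(r1$oof, r2$oof)
})

test_that("a perfectly separating feature yields near-perfect nested AUROC", {
  set.seed(66)
  n <- 60
  x <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:20)))
  y <- rep(c(0, 1), each = n / 2)
  x[, 1] <- y * 2 + rnorm(n, 0, 0.05)
  rep1 <- microgba:::nested_cv_xy(x, y,
                                  model_spec("lasso_logistic",
                                             search_budget = 4),
                                  repeats = 2, outer_folds = 5,
                                  inner_folds = 3, seed = 12)
  expect_gte(rep1$mean_auroc, 0.95)
})

test_that("every sample gets exactly one out-of-fold prediction per repeat", {
  ds <- simulate_dataset(sim_params(n_studies = 1, n_cases = 15,
                                    n_controls = 15, n_taxa = 30, seed = 67))
  rep1 <- nested_cv(ds, model_spec("logistic", feature_grid = c(4, 8)),
                    repeats = 3, seed = 13)
  counts <- table(rep1$oof$repeat_id, rep1$oof$sample_id)
  expect_true(all(counts == 1))
  expect_true(all(rep1$fold_metrics$auroc >= 0 & rep1$fold_metrics$auroc <= 1))
})

test_that("LOCO holds out whole cohorts and reflects heterogeneity", {
  spec <- model_spec("lasso_logistic", search_budget = 4)
  ds <- simulate_dataset(sim_params(n_studies = 5, n_cases = 20,
                                    n_controls = 20, n_taxa = 60,
                                    effect_size = 2, batch_sd = 0.2,
                                    seed = 68))
  lr <- loco_cv(ds, spec, seed = 14)
  expect_true(all(lr$per_cohort$auroc >= 0.9))
  # out-of-cohort contract: every sample predicted exactly once
  expect_setequal(lr$oof$sample_id, ds$profiles$sample_id)

  # invert the planted effect in one cohort (by swapping its case/control
  # labels): its held-out AUROC collapses while the majority-signal
  # cohorts stay discriminable
  flip <- ds$samples$study_id == "study05"
  md <- ds$samples
  md$is_case[flip] <- !md$is_case[flip]
  md$disease[flip] <- ifelse(md$is_case[flip], "PD", "healthy")
  ds_flip <- mgba_dataset(ds$profiles, md)
  lr_flip <- loco_cv(ds_flip, spec, seed = 14)
  expect_lt(lr_flip$per_cohort$auroc[lr_flip$per_cohort$cohort == "study05"],
            0.5)
  expect_gt(min(lr_flip$per_cohort$auroc[lr_flip$per_cohort$cohort != "study05"]),
            0.75)

  ds2 <- simulate_dataset(sim_params(n_studies = 2, n_cases = 10,
                                     n_controls = 10, n_taxa = 30, seed = 69))
  expect_error(loco_cv(ds2, spec), "at least 3 cohorts")
})

test_that("final-model AUROCs follow the expected optimism ordering", {
  spec <- model_spec("lasso_logistic", search_budget = 4)
  ordering_ok <- vapply(1:5, function(i) {
    ds <- simulate_dataset(sim_params(n_studies = 1, n_cases = 25,
                                      n_controls = 25, n_taxa = 60,
                                      effect_size = 1, seed = 70 + i))
    rep1 <- nested_cv(ds, spec, repeats = 2, seed = i)
    fm <- tune_final(ds, consensus_features(rep1), spec, seed = i)
    fm$final_fit_auroc >= rep1$mean_auroc - 0.05
  }, logical(1))
  expect_gte(stats::median(ordering_ok), 1)

  # a single separable feature gives a perfect resubstitution fit
  set.seed(71)
  n <- 40
  m <- cbind(sep = rep(c(0.2, 0.001), each = n / 2),
             noise = runif(n, 0, 0.01))
  ids <- sprintf("s%02d", 1:n)
  rownames(m) <- ids
  ds_sep <- mgba_dataset(
    dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(m)),
    tibble::tibble(sample_id = ids, study_id = "a",
                   disease = rep(c("PD", "healthy"), each = n / 2),
                   is_case = rep(c(TRUE, FALSE), each = n / 2)))
  fm_sep <- tune_final(ds_sep, "sep", model_spec("logistic"), seed = 2)
  expect_equal(fm_sep$final_fit_auroc, 1)
})

test_that("cross-study transfer degrades under planted batch bias", {
  spec <- model_spec("lasso_logistic", search_budget = 4)
  ds_hom <- simulate_dataset(sim_params(n_studies = 2, n_cases = 25,
                                        n_controls = 25, n_taxa = 60,
                                        effect_size = 2, batch_sd = 0,
                                        seed = 80))
  hom <- cross_study_validation(ds_hom, spec, repeats = 2, seed = 3)
  expect_gt(hom$mean_off_diagonal, hom$mean_diagonal - 0.1)

  ds_bias <- simulate_dataset(sim_params(n_studies = 2, n_cases = 25,
                                         n_controls = 25, n_taxa = 60,
                                         effect_size = 1, batch_sd = 2,
                                         seed = 81))
  bias <- cross_study_validation(ds_bias, spec, repeats = 2, seed = 3)
  expect_gte(bias$mean_diagonal - bias$mean_off_diagonal, 0.1)

  ds_one <- simulate_dataset(sim_params(n_studies = 1, n_cases = 10,
                                        n_controls = 10, n_taxa = 30,
                                        seed = 82))
  expect_error(cross_study_validation(ds_one, spec), "at least 2 studies")
})

test_that("models are disease specific unless signatures are shared", {
  spec <- model_spec("lasso_logistic", search_budget = 4)
  ds_a <- simulate_dataset(sim_params(n_studies = 1, n_cases = 40,
                                      n_controls = 40, disease = "PD",
                                      seed = 83))
  fm <- tune_final(ds_a, names(ds_a$truth$disease_taxa), spec, seed = 4)

  # a foreign disease with its own (disjoint) planted taxa: near chance
  # (the band allows for mild compositional spillover of the foreign
  # disease's planted effects into the model's features)
  ds_b <- simulate_dataset(sim_params(n_studies = 1, n_cases = 40,
                                      n_controls = 40, disease = "MDD",
                                      seed = 84))
  shared <- intersect(names(ds_a$truth$disease_taxa),
                      names(ds_b$truth$disease_taxa))
  expect_length(shared, 0)  # the two seeds plant disjoint taxa
  res <- cross_disease_specificity(fm, list(ds_b))
  expect_gt(res$auroc, 0.35)
  expect_lt(res$auroc, 0.65)

  # the same truth resimulated (shared signature): stays high
  ds_c <- inject_external_cohort(
    sim_params(n_studies = 1, n_cases = 40, n_controls = 40,
               batch_sd = 0, seed = 100),
    ds_a$truth)
  pr <- predict(fm, ds_c)
  expect_gt(auroc(pr$probability, ds_c$samples$is_case), 0.85)

  # scoring the training data reproduces the (optimistic) fit-level AUROC
  pr_self <- predict(fm, ds_a)
  expect_gte(auroc(pr_self$probability, ds_a$samples$is_case),
             fm$tuning_auroc - 0.05)
})

test_that("missing features at prediction time are zero-imputed with a note", {
  ds <- simulate_dataset(sim_params(n_studies = 1, n_cases = 15,
                                    n_controls = 15, n_taxa = 30,
                                    effect_size = 2, seed = 86))
  fm <- tune_final(ds, taxa_names(ds)[1:10],
                   model_spec("lasso_logistic", search_budget = 2), seed = 5)
  reduced <- taxon_matrix(ds)[, -1]
  expect_message(predict(fm, reduced), "imputed as 0")
})
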