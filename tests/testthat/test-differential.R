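test_that("abundance-mode effects recover a planted log10 deficit", {
  # one cohort, one taxon with a -1 log10 shift in cases, log-normal noise
  set.seed(50)
  hits <- 0
  for (rep_i in 1:20) {
    n <- 50
    log_ab <- c(rnorm(n, -3, 0.5), rnorm(n, -2, 0.5))  # cases first
    m <- matrix(10^log_ab, ncol = 1, dimnames = list(NULL, "tx"))
    filler <- matrix(0.01, 2 * n, 1, dimnames = list(NULL, "other"))
    ids <- sprintf("s%03d", seq_len(2 * n))
    ds <- mgba_dataset(
      dplyr::bind_cols(tibble::tibble(sample_id = ids),
                       tibble::as_tibble(cbind(m, filler))),
      tibble::tibble(sample_id = ids, study_id = "c1",
                     disease = rep(c("MDD", "healthy"), each = n),
                     is_case = rep(c(TRUE, FALSE), each = n)))
    res <- cohort_association(ds, "abundance", pseudocount = 1e-6)
    eff <- res$effect[res$taxon == "tx"]
    if (abs(eff - (-1)) <= 0.2) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("abundance-mode tests hold their level under permuted labels", {
  ds <- simulate_dataset(sim_params(
    n_studies = 1, n_cases = 30, n_controls = 30, n_taxa = 500,
    n_disease_taxa = 0, effect_size = 0, batch_sd = 0, seed = 51
  ))
  res <- cohort_association(ds, "abundance")
  reject <- mean(res$p < 0.05, na.rm = TRUE)
  expect_gte(reject, 0.02)
  expect_lte(reject, 0.08)
})

test_that("prevalence mode flags constant taxa and survives separation", {
  set.seed(52)
  n <- 30
  m <- cbind(
    everywhere = rep(0.01, 2 * n),
    informative = c(stats::rbinom(n, 1, 0.9), stats::rbinom(n, 1, 0.2)) * 0.01,
    separated = rep(c(0.01, 0), each = n)
  )
  ids <- sprintf("s%03d", seq_len(2 * n))
  rownames(m) <- ids
  ds <- mgba_dataset(
    dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(m)),
    tibble::tibble(sample_id = ids, study_id = "c1",
                   disease = rep(c("SCZ", "healthy"), each = n),
                   is_case = rep(c(TRUE, FALSE), each = n)))
  res <- cohort_association(ds, "prevalence")
  expect_false(res$estimable[res$taxon == "everywhere"])
  info <- res[res$taxon == "informative", ]
  expect_true(info$estimable)
  expect_gt(info$effect, 0)
  expect_lt(info$p, 0.01)
  sep <- res[res$taxon == "separated", ]
  expect_true(sep$estimable)       # Firth fallback keeps it finite
  expect_true(is.finite(sep$effect) && is.finite(sep$se))
  expect_gt(sep$effect, 0)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(53)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("DerSimonian-Laird pooling matches closed forms and metafor", {
  # equal effects and ses: pooled = e, tau2 = 0, se = s/sqrt(k)
  res <- random_effects_pool(rep(1.3, 2), rep(0.2, 2))
  expect_equal(res$effect, 1.3)
  expect_equal(res$tau_squared, 0)
  expect_equal(res$se, 0.2 / sqrt(2), tolerance = 1e-12)
  res5 <- random_effects_pool(rep(-0.4, 5), rep(0.15, 5))
  expect_equal(res5$effect, -0.4)
  expect_equal(res5$se, 0.15 / sqrt(5), tolerance = 1e-12)

  # opposite effects: heterogeneity absorbed into tau2, pooled ~ 0
  opp <- random_effects_pool(c(1, -1), c(0.1, 0.1))
  expect_gt(opp$tau_squared, 0)
  expect_equal(opp$effect, 0, tolerance = 1e-12)
  orc <- dl_oracle(c(1, -1), c(0.1, 0.1))
  expect_equal(opp$effect, orc$effect, tolerance = 1e-10)
  expect_equal(opp$se, orc$se, tolerance = 1e-10)
  expect_equal(opp$tau_squared, orc$tau2, tolerance = 1e-10)

  # single cohort: pass-through, flagged
  single <- random_effects_pool(0.8, 0.3)
  expect_false(single$pooled)
  expect_equal(single$effect, 0.8)

  skip_if_not_installed("metafor")
  set.seed(54)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    e <- rnorm(k)
    s <- runif(k, 0.05, 0.5)
    mine <- random_effects_pool(e, s)
    ref <- metafor::rma(yi = e, sei = s, method = "DL")
    expect_equal(mine$effect, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(mine$se, ref$se, tolerance = 1e-10)
    expect_equal(mine$tau_squared, ref$tau2, tolerance = 1e-10)
  }
})

test_that("pooled results are invariant to cohort order", {
  ds <- simulate_dataset(sim_params(n_studies = 3, n_cases = 10,
                                    n_controls = 10, n_taxa = 30, seed = 55))
  assoc <- associate_cohorts(ds, "abundance")
  pooled1 <- pool_associations(assoc)
  pooled2 <- pool_associations(assoc[order(assoc$cohort, decreasing = TRUE), ])
  expect_equal(pooled1, pooled2)
})

test_that("cross-disease direction classification follows sign agreement", {
  pooled <- tibble::tibble(
    taxon = c("t1", "t1", "t1", "t2", "t2", "t3", "t3"),
    disease = c("PD", "SCZ", "MDD", "PD", "MDD", "PD", "MDD"),
    mode = "abundance",
    effect = c(-1, -0.5, -0.2, -1, 1, 0.3, 0.4),
    q = c(0.01, 0.05, 0.2, 0.01, 0.05, 0.5, 0.9)
  )
  cls <- classify_directions(pooled, q_threshold = 0.1)
  expect_equal(cls$category[cls$taxon == "t1"], "consistent_health")
  expect_equal(cls$category[cls$taxon == "t2"], "context_dependent")
  expect_equal(cls$category[cls$taxon == "t3"], "not_significant")
  expect_equal(cls$diseases_significant[cls$taxon == "t1"], "PD,SCZ")
})

test_that("the pooled pipeline controls FDR under the global null", {
  # 100 small null replicates: average realized false-discovery proportion
  # at q < 0.1 stays at or below 0.15
  fdp <- vapply(1:100, function(i) {
    ds <- simulate_dataset(sim_params(
      n_studies = 3, n_cases = 12, n_controls = 12, n_taxa = 60,
      n_disease_taxa = 0, batch_sd = 0.2, seed = 1000 + i
    ))
    pooled <- pool_associations(associate_cohorts(ds, "abundance"))
    disc <- sum(pooled$q < 0.1, na.rm = TRUE)
    if (disc == 0) 0 else disc / disc  # all discoveries are false here
  }, numeric(1))
  expect_lte(mean(fdp), 0.15)
})
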