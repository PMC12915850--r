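test_that("the Youden threshold matches an exhaustive scan", {
  set.seed(90)
  for (i in 1:100) {
    n <- sample(8:40, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    prob <- round(runif(n), 2)  # duplicates force tie handling
    t_star <- youden_threshold(prob, labels)
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    j_at <- function(t) {
      sum(prob >= t & labels == 1) / n1 + sum(prob < t & labels == 0) / n0 - 1
    }
    expect_equal(j_at(t_star), youden_oracle(prob, labels), tolerance = 1e-12)
    expect_gt(t_star, 0); expect_lt(t_star, 1)
  }
})

test_that("separable scores put the threshold strictly inside the gap", {
  prob <- c(0.9, 0.8, 0.7, 0.1)
  labels <- c(1, 1, 0, 0)
  t_star <- youden_threshold(prob, labels)
  expect_gt(t_star, 0.7)
  expect_lt(t_star, 0.8)
  # J = 1 at the returned cut
  expect_equal(sum(prob >= t_star & labels == 1) / 2 +
                 sum(prob < t_star & labels == 0) / 2 - 1, 1)
  # ties in J break toward higher sensitivity (the lower cut)
  prob2 <- c(0.9, 0.6, 0.4, 0.1)
  labels2 <- c(1, 1, 0, 0)
  expect_equal(youden_threshold(prob2, labels2), 0.5)
  # inverted labels attain the same |J| optimum via the complementary rule
  j_inv <- youden_oracle(prob, 1 - labels) # degenerate rule, J >= 0 always
  expect_gte(j_inv, 0)
  expect_error(youden_threshold(c(0.2, 0.4), c(1, 1)), "both classes")
})

test_that("the index is the threshold-centered reflection of probability", {
  expect_equal(mgba_hi(0.37, 0.37), 0)
  expect_equal(mgba_hi(0, 0.37), 0.37)
  expect_equal(mgba_hi(1, 0.37), -0.63)
  # sign contract, exhaustively on a dense grid
  th <- 0.41
  p <- seq(0, 1, by = 1e-4)
  idx <- mgba_hi(p, th)
  expect_true(all((idx > 0) == (p < th)))
})

test_that("Cliff's delta matches enumeration, bounds and antisymmetry", {
  expect_equal(cliffs_delta(c(2, 2), c(2, 2)), 0)
  expect_equal(cliffs_delta(c(1, 2), c(5, 6)), -1)
  expect_equal(cliffs_delta(c(5, 6), c(1, 2)), 1)
  expect_equal(cliffs_delta(c(1, 3), c(2, 2)), 0)
  set.seed(91)
  for (i in 1:100) {
    x <- sample(1:6, sample(3:10, 1), TRUE)
    y <- sample(1:6, sample(3:10, 1), TRUE)
    d <- cliffs_delta(x, y)
    expect_equal(d, cliffs_oracle(x, y), tolerance = 1e-12)
    expect_equal(d, -cliffs_delta(y, x), tolerance = 1e-12)
    expect_gte(d, -1); expect_lte(d, 1)
    # invariance under a strictly increasing transform
    expect_equal(cliffs_delta(exp(x), exp(y)), d, tolerance = 1e-12)
  }
})

test_that("index evaluation handles extremes and degenerate input", {
  labels <- rep(c(1, 0), each = 10)
  ev <- evaluate_index(1 - labels, labels)  # index == health indicator
  expect_equal(ev$group_test$cliffs_delta, -1)
  expect_lt(ev$group_test$wilcoxon_p, 1e-4)

  idx <- c(rnorm(10), rnorm(10, 2))
  ev2 <- evaluate_index(idx, labels,
                        phenotypes = tibble::tibble(mirror = -idx),
                        n_boot = 200, seed = 1)
  pc <- ev2$phenotype_correlations
  expect_equal(pc$rho, -1)
  expect_equal(pc$ci_lower, -1)
  expect_equal(pc$ci_upper, -1)

  ev3 <- evaluate_index(rep(0.5, 20), labels)
  expect_true(ev3$group_test$degenerate)
  expect_equal(ev3$group_test$wilcoxon_p, 1)

  # monotone invariance of the rank statistics
  set.seed(92)
  idx4 <- rnorm(20)
  a <- evaluate_index(idx4, labels)
  b <- evaluate_index(exp(idx4), labels)
  expect_equal(a$group_test$wilcoxon_p, b$group_test$wilcoxon_p,
               tolerance = 1e-12)
  expect_equal(a$group_test$cliffs_delta, b$group_test$cliffs_delta,
               tolerance = 1e-12)
})

test_that("bootstrap CIs for independent phenotypes cover zero at the nominal rate", {
  set.seed(93)
  covered <- vapply(1:100, function(i) {
    idx <- rnorm(50)
    ph <- rnorm(50)
    ev <- evaluate_index(idx, rep(c(0, 1), 25),
                         phenotypes = tibble::tibble(ph = ph), n_boot = 200)
    pc <- ev$phenotype_correlations
    pc$ci_lower <= 0 && 0 <= pc$ci_upper
  }, logical(1))
  expect_gte(mean(covered), 0.85)
  expect_lte(mean(covered), 1)
})

test_that("index_for_dataset prefers out-of-cohort probabilities and errors otherwise", {
  ds <- simulate_dataset(sim_params(n_studies = 3, n_cases = 12,
                                    n_controls = 12, n_taxa = 40,
                                    effect_size = 2, seed = 94))
  spec <- model_spec("lasso_logistic", search_budget = 3)
  lr <- loco_cv(ds, spec, seed = 6)
  idx <- index_for_dataset(ds, loco_report = lr)
  expect_true(all(idx$source == "out_of_cohort"))
  expect_equal(idx$index,
               attr(idx, "threshold") - idx$probability, tolerance = 1e-12)
  # single explicit probability/threshold arithmetic
  one <- index_for_dataset(subset_samples(ds, 1), loco_report = lr,
                           threshold = 0.5)
  expect_equal(one$index, 0.5 - one$probability)
  # no source at all
  ext <- inject_external_cohort(sim_params(n_studies = 1, n_cases = 5,
                                           n_controls = 5, n_taxa = 40,
                                           seed = 95), ds$truth)
  expect_error(index_for_dataset(ext, loco_report = lr), "neither")
})
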