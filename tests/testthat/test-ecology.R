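test_that("shannon matches analytic values and a direct summation oracle", {
  expect_equal(shannon(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon(c(0, 7, 0)), 0)
  p <- c(0.5, 0.3, 0.2)
  expect_equal(shannon(p), -sum(p * log(p)), tolerance = 1e-12)
  expect_error(shannon(c(0, 0)), "all-zero")
  # vegan agreement on random compositions
  skip_if_not_installed("vegan")
  set.seed(1)
  for (i in 1:20) {
    v <- rexp(10)
    expect_equal(shannon(v), unname(vegan::diversity(v, "shannon")),
                 tolerance = 1e-10)
  }
})

test_that("pairwise dissimilarities match their formulas and vegan", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0, 0), c(0, 2, 3)), 1)
  expect_equal(bray_curtis(c(0.6, 0.4, 0), c(0.2, 0.4, 0.4)), 0.4,
               tolerance = 1e-12)
  expect_equal(jaccard(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)
  expect_equal(jaccard(c(1, 2), c(3, 4)), 0)
  expect_equal(jaccard(c(1, 0), c(0, 1)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all zero")
  expect_error(jaccard(c(0, 0), c(0, 0)), "empty")

  skip_if_not_installed("vegan")
  set.seed(2)
  m <- matrix(rexp(8 * 12), 8, 12)
  m[m < 0.3] <- 0
  d_bc <- dissimilarity_matrix(m, "bray_curtis")$matrix
  d_j <- dissimilarity_matrix(m, "jaccard")$matrix
  expect_equal(d_bc, as.matrix(vegan::vegdist(m, "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(d_j, as.matrix(vegan::vegdist(m, "jaccard", binary = TRUE)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("dissimilarities are symmetric and bounded on random inputs", {
  set.seed(3)
  for (i in 1:1000) {
    x <- rexp(6) * rbinom(6, 1, 0.7)
    y <- rexp(6) * rbinom(6, 1, 0.7)
    if (sum(x + y) == 0) next
    b <- bray_curtis(x, y)
    expect_gte(b, 0); expect_lte(b, 1)
    expect_identical(b, bray_curtis(y, x))
    if (sum(x > 0 | y > 0) > 0) {
      j <- jaccard(x, y)
      expect_gte(j, 0); expect_lte(j, 1)
      expect_identical(j, jaccard(y, x))
    }
  }
})

test_that("pcoa recovers planted Euclidean geometry and satisfies the trace identity", {
  set.seed(4)
  pts <- matrix(rnorm(10 * 2), 10, 2)
  d <- as.matrix(stats::dist(pts))
  res <- pcoa(d)
  co <- as.matrix(res$coordinates[-1])
  # distances between recovered coordinates reproduce the input exactly
  expect_lt(max(abs(as.matrix(stats::dist(co[, 1:2])) - d)), 1e-8)
  # trace identity: sum of eigenvalues = trace of the centered Gower matrix
  a <- -0.5 * d^2
  g <- t(t(a - rowMeans(a)) - colMeans(a)) + mean(a)
  expect_equal(sum(res$eigenvalues), sum(diag(g)), tolerance = 1e-9)
  # three equidistant points: two equal positive eigenvalues
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  e3 <- pcoa(tri)$eigenvalues
  expect_equal(e3[1], e3[2], tolerance = 1e-12)
  expect_error(pcoa(tri[1:2, 1:2]), "at least 3")

  skip_if_not_installed("ape")
  bc <- dissimilarity_matrix(taxon_matrix(toy_dataset(seed = 6)), "bray_curtis")
  ref <- ape::pcoa(as.dist(bc$matrix))
  mine <- pcoa(bc)
  k <- min(3, ncol(ref$vectors))
  for (ax in 1:k) {
    expect_equal(abs(as.matrix(mine$coordinates[-1])[, ax]),
                 abs(ref$vectors[, ax]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("permanova agrees with vegan::adonis2 and its own R2 identity", {
  skip_if_not_installed("vegan")
  ds <- toy_dataset(n = 16, n_taxa = 10, seed = 7)
  d <- dissimilarity_matrix(ds, "bray_curtis")
  g <- ds$samples$study_id
  mine <- permanova(d, g, n_permutations = 99, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(d$matrix) ~ g, permutations = 99)
  expect_equal(mine$r_squared, ref$R2[1], tolerance = 1e-10)
  expect_equal(mine$pseudo_f, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$r_squared, 1 - mine$ss_within / mine$ss_total,
               tolerance = 1e-12)
  # invariance to relabeling of group names
  relab <- permanova(d, ifelse(g == "A", "zzz", "aaa"),
                     n_permutations = 99, seed = 1)
  expect_equal(relab$r_squared, mine$r_squared, tolerance = 1e-12)
  expect_equal(relab$pseudo_f, mine$pseudo_f, tolerance = 1e-12)
})

test_that("permanova handles degenerate and separated designs", {
  # zero within-group distance -> R2 = 1
  m <- rbind(a1 = c(1, 0), a2 = c(1, 0), b1 = c(0, 1), b2 = c(0, 1))
  d <- dissimilarity_matrix(m, "bray_curtis")
  res <- permanova(d, c("a", "a", "b", "b"), n_permutations = 99, seed = 1)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)

  # two well-separated clusters: minimal attainable p
  set.seed(8)
  big <- rbind(matrix(rnorm(10 * 3, 0, 0.01), 10),
               matrix(rnorm(10 * 3, 5, 0.01), 10))
  dd <- as.matrix(stats::dist(big))
  res2 <- permanova(dd, rep(c("x", "y"), each = 10),
                    n_permutations = 199, seed = 2)
  expect_equal(res2$p_value, 1 / 200)
  expect_error(permanova(dd, c("x", rep("y", 19))), "at least 2 samples")
})

test_that("within-group dissimilarity comparison detects inflated case heterogeneity", {
  # identical compositions everywhere -> degenerate, p = 1
  m <- matrix(rep(c(0.5, 0.5), each = 8), 8, 2)
  rownames(m) <- paste0("s", 1:8)
  d <- dissimilarity_matrix(m, "bray_curtis")
  g <- rep(c("case", "control"), each = 4)
  res <- within_group_dissimilarity_test(d, g)
  expect_equal(res$p_value, 1)
  expect_equal(res$median_difference, 0)

  # doubled log-noise in cases -> larger within-case dissimilarities
  set.seed(9)
  n <- 35
  cases <- exp(matrix(rnorm(n * 20, 0, 2), n))
  ctrls <- exp(matrix(rnorm(n * 20, 0, 1), n))
  m2 <- rbind(cases, ctrls)
  m2 <- m2 / rowSums(m2)
  rownames(m2) <- paste0("s", seq_len(2 * n))
  d2 <- dissimilarity_matrix(m2, "bray_curtis")
  g2 <- rep(c("case", "control"), each = n)
  res2 <- within_group_dissimilarity_test(d2, g2)
  expect_gt(res2$median_difference, 0)
  expect_lt(res2$p_value, 0.05)
  # swapping labels flips the sign
  res3 <- within_group_dissimilarity_test(
    d2, ifelse(g2 == "case", "control", "case"))
  expect_equal(res3$median_difference, -res2$median_difference,
               tolerance = 1e-12)
})
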