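# Shared fixture builders. Everything is generated in code; nothing binary.

# Tiny hand-built dataset: `n` samples split across `studies`, abundances
# drawn from a seeded Dirichlet-like draw scaled to (1 - unclassified).
toy_dataset <- function(n = 12, n_taxa = 6, studies = c("A", "B"), seed = 1,
                        healthy_label = "healthy") {
  set.seed(seed)
  uf <- runif(n, 0.05, 0.15)
  m <- matrix(rexp(n * n_taxa), n, n_taxa)
  m <- m / rowSums(m) * (1 - uf)
  taxa <- sprintf("s__Tax%02d", seq_len(n_taxa))
  colnames(m) <- taxa
  ids <- sprintf("samp%02d", seq_len(n))
  rownames(m) <- ids
  is_case <- rep(c(TRUE, FALSE), length.out = n)
  samples <- tibble::tibble(
    sample_id = ids,
    study_id = rep(studies, length.out = n),
    disease = ifelse(is_case, "PD", healthy_label),
    is_case = is_case,
    age = round(runif(n, 20, 70), 1),
    sex = sample(c("F", "M"), n, TRUE),
    bmi = round(runif(n, 19, 28), 1),
    read_count = round(runif(n, 1.5e7, 4e7)),
    unclassified_fraction = uf
  )
  profiles <- dplyr::bind_cols(tibble::tibble(sample_id = ids),
                               tibble::as_tibble(m))
  mgba_dataset(profiles, samples, healthy_label = healthy_label)
}

# A small MetaPhlAn-style merged table written to a temp file; returns the
# path. Contains one comment line, genus- and species-level clades, and
# percent units.
toy_metaphlan_file <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "#mpa_toy_version",
    "clade_name\tsampleA\tsampleB",
    "k__Bacteria\t100\t100",
    "k__Bacteria|g__Alpha\t60\t30",
    "k__Bacteria|g__Alpha|s__Alpha_one\t35\t10",
    "k__Bacteria|g__Alpha|s__Alpha_two\t25\t20",
    "k__Bacteria|g__Beta|s__Beta_one\t40\t70"
  ), path)
  path
}

# Brute-force BH step-up oracle: q_(i) = min_{j >= i} p_(j) * n / j.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  ps <- p[o]
  for (i in seq_len(n)) {
    q_sorted[i] <- min(ps[i:n] * n / (i:n), 1)
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Pairwise-enumeration Cliff's delta oracle.
cliffs_oracle <- function(x, y) {
  gt <- 0; lt <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) gt <- gt + 1 else if (xi < yj) lt <- lt + 1
  }
  (gt - lt) / (length(x) * length(y))
}

# Exhaustive Youden oracle: best J over all cuts (including below/above all
# observed probabilities), predicted positive when prob >= t.
youden_oracle <- function(prob, labels) {
  cuts <- sort(unique(c(0, prob, 1 + 1e-9)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  j <- vapply(cuts, function(t) {
    sum(prob >= t & labels == 1) / n1 + sum(prob < t & labels == 0) / n0 - 1
  }, numeric(1))
  max(j)
}

# Mann-Whitney pair-counting AUROC oracle.
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + (p > q) + 0.5 * (p == q)
  }
  s / (length(pos) * length(neg))
}

# DerSimonian-Laird oracle written straight from the moment formulas.
dl_oracle <- function(e, s) {
  w <- 1 / s^2
  ebar <- sum(w * e) / sum(w)
  q <- sum(w * (e - ebar)^2)
  tau2 <- max(0, (q - (length(e) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (s^2 + tau2)
  list(effect = sum(ws * e) / sum(ws), se = sqrt(1 / sum(ws)), tau2 = tau2)
}
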