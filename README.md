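# microgba

Multi-cohort microbiome analysis along the microbiota–gut–brain axis:
quality control, community ecology, batch correction, differential
meta-analysis, leakage-safe classifier evaluation, and a per-sample
health index.

## The problem

Single-cohort case-control microbiome studies of neuropsychiatric
disorders are small, confounded by study-level technical variation
("batch effects"), and notorious for optimistic machine-learning results
caused by information leakage between feature selection and evaluation.
`microgba` packages the analysis machinery needed to do this properly
across many cohorts at once, for anyone working with species-level
relative-abundance profiles (MetaPhlAn-style merged tables) and
harmonized per-sample metadata:

* **QC** — sample filters (≥ 10 M reads, ≤ 30% unclassified, BMI ≤ 30),
  whole-study removal below 10 samples, and species refinement at a
  1e-4 abundance / 1% occurrence threshold, with a complete audit trail.
* **Ecology** — Shannon diversity, Bray–Curtis and Jaccard
  dissimilarities, PCoA, and one-factor PERMANOVA
  (R² = 1 − SS_within/SS_total, add-one permutation p, 999 permutations).
* **Batch correction** — a covariate-preserving empirical-Bayes
  (ComBat-family) corrector on log10 abundances, plus a harness scoring
  any correction by the percent reduction in PERMANOVA batch R².
* **Differential meta-analysis** — per-cohort abundance (linear on log10)
  and prevalence (logistic, Firth fallback under separation) models,
  DerSimonian–Laird random-effects pooling, Benjamini–Hochberg control at
  FDR < 0.1, and cross-disease direction classification.
* **Leakage-safe model evaluation** — 10×-repeated 5-fold *nested*
  cross-validation (feature selection and hyperparameter tuning strictly
  inside the inner loop), leave-one-cohort-out (LOCO) validation,
  final-model fitting with tuning/resubstitution AUROCs labeled for what
  they are, cross-study, external and cross-disease evaluation.
* **MGBA-HI** — a health index `threshold − P(disease)`, centered at the
  Youden-optimal cut (max sensitivity + specificity − 1) of out-of-cohort
  predicted probabilities; evaluated by Wilcoxon rank-sum tests, Cliff's
  delta (disease vs health; negative = lower in patients) and
  bootstrap-CI Spearman correlations against phenotypes.
* **Core protective taxa** — the intersection of consistently
  health-enriched taxa, health-direction classifier features, and taxa
  prevalent in ≥ 50% of healthy individuals.
* **Synthetic cohorts** — a zero-inflated log-normal generator with
  per-study multiplicative bias and planted disease effects, so every
  stage can be validated against known ground truth.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`s.

## Worked example

```r
library(microgba)

# three cohorts of 50 cases + 50 controls, 200 species, 10 planted
# disease taxa (5 protective), study-level batch bias
ds <- simulate_dataset(sim_params(seed = 800))
ds
#> <mgba_dataset> 300 samples x 200 taxa, 3 studies (study01, study02, study03)
#>   cases: 150, controls: 150; diseases: PD
#>   planted truth: 10 disease taxa (5 protective)

# leave-one-cohort-out evaluation of a lasso classifier
spec <- model_spec("lasso_logistic", search_budget = 8)
lr <- loco_cv(ds, spec, seed = 8)
lr
#> <loco_report> lasso_logistic: mean per-cohort AUROC = 0.923 over 3 cohorts
#> # A tibble: 3 × 4
#>   cohort  auroc     n n_features
#>   <chr>   <dbl> <int>      <int>
#> 1 study01 0.944   100         16
#> 2 study02 0.953   100         32
#> 3 study03 0.872   100         64

# the health index, scored with out-of-cohort probabilities only
thr <- youden_threshold(lr$oof$probability, lr$oof$label)
idx <- index_for_dataset(ds, loco_report = lr, threshold = thr)
evaluate_index(idx$index, ds$samples$is_case)
#> index: case median -0.210 vs control median 0.334; rank-sum p = 2.39e-33;
#> Cliff's delta = -0.804
```

Each held-out cohort is scored by a model that never saw it, so the
AUROCs estimate cross-population generalization, not fit. The index is
positive for healthy-like samples (predicted disease probability below
the Youden threshold); the strongly negative Cliff's delta says patients
score systematically lower, as planted.

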