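---
title: "Methods: multi-cohort microbiome classification and the MGBA-HI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort microbiome classification and the MGBA-HI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microgba)
```

## Scope and data model

`microgba` analyzes multi-study case-control collections of species-level
relative-abundance profiles — the kind of table a shotgun-metagenomic
profiler emits — together with harmonized per-sample metadata. Everything
revolves around one container, the `mgba_dataset`: a samples-by-taxa tibble
of fractions (per-sample sums may fall short of 1; the remainder is the
unclassified portion of the community), a metadata tibble (study, disease,
case/control status, age, sex, BMI, read count, unclassified fraction,
optional phenotype scores), and — for simulated data — the planted ground
truth. Abundances are held as fractions internally; percent-scaled merged
tables are converted on ingest, and species-level rows are recognized by
the deepest clade-rank prefix (`s__`), which is robust to
genome-bin-style names. Missing metadata is never dropped at read time:
each statistical routine removes only the records missing a field it
actually uses.

## Quality control

The sample filters are the conventional ones for cross-study shotgun
meta-analysis, applied in a fixed order with a full audit trail: read
count below 10 million, unclassified fraction above 30%, BMI above
30 kg/m² (obesity is a strong microbiome confounder; missing BMI never
excludes), then removal of whole studies left with fewer than 10 samples.
Each excluded sample is recorded with the *first* rule that caught it, so
the audit reconciles exactly with the input.

Species are refined jointly by a 1e-4 relative-abundance detection limit
and a 1% occurrence threshold: a taxon survives iff it reaches the
detection limit in at least 1% of samples, and sub-detection values in
surviving taxa are zeroed. We deliberately do not re-close compositions
after species filtering, so absolute fractions remain comparable across
filter settings; `analysis_config(renormalize = TRUE)` enables the
alternative, and `occurrence_on_nonzero = TRUE` switches occurrence to
counting any nonzero value. The unclassified-fraction rule uses the
recorded per-sample `unclassified_fraction` field, not 1 minus the species
sum.

## Community ecology

Shannon diversity (natural log), Bray-Curtis and Jaccard dissimilarities,
and classical PCoA are computed from their defining formulas (each is
cross-checked against an independent implementation in the test suite).
PCoA reports negative eigenvalues rather than silently dropping them,
since Bray-Curtis matrices are generally non-Euclidean.

PERMANOVA is the one-factor permutation test on a dissimilarity matrix:
with $N$ samples in $a$ groups,
$SS_{total} = \tfrac1N \sum_{i<j} d_{ij}^2$,
$SS_{within} = \sum_g \tfrac1{n_g}\sum_{i<j \in g} d_{ij}^2$,
$R^2 = 1 - SS_{within}/SS_{total}$, and the pseudo-$F$ compares the
between/within mean squares. The p-value uses the add-one convention
$(1 + \#\{F_{perm} \ge F_{obs}\})/(1 + B)$ with $B = 999$ permutations by
default, so 0 is never reported. Labels permute freely; a `strata`
argument restricts permutations within blocks for pooled designs. Only the
one-factor design is implemented — both uses in the workflow (disease
status, batch membership) are one-factor questions.

The claim that disease communities are more heterogeneous is
operationalized by `within_group_dissimilarity_test()`: all within-case
and within-control pairwise dissimilarities are compared by a two-sided
Wilcoxon rank-sum test. Comparing within-group sets (rather than
case-to-control distances) is an interpretive choice; both views are
available since the dissimilarity matrix is returned whole.

## Batch correction

`eb_batch_correct()` is a covariate-preserving empirical-Bayes corrector
of the ComBat family, operating on $y = \log_{10}(a + c)$ with
pseudocount $c = 5\times10^{-5}$ (half the detection limit). Per taxon it
fits batch indicators plus the case/control covariate, standardizes the
residual variance, shrinks per-batch locations toward a normal prior and
per-batch scales toward a moment-matched inverse-gamma prior (estimated
across taxa), removes the shrunken batch effects, and restores the
covariate fit and grand mean. Back-transformed values are clipped at zero;
compositions are *not* re-closed (the correction is additive on logs, and
re-closure would reintroduce cross-taxon coupling — `reclose = TRUE`
enables it). A non-parametric variant (`parametric = FALSE`) replaces the
parametric posteriors with likelihood-weighted empirical priors, which is
more conservative on heavily zero-inflated taxa. Batches must each contain
both classes: a batch perfectly confounded with the covariate is
uncorrectable and raises an error naming it.

Correction quality is scored by `batch_variance_reduction()`: the percent
drop in the PERMANOVA batch $R^2$ on Bray-Curtis dissimilarities. Because
the harness only needs two datasets with matching samples, it can score
any external corrector's output table, not just this one's.

## Differential analysis and meta-analytic pooling

Per-cohort association is intentionally the simplest pair of models
honoring the two data modes: ordinary least squares of
$\log_{10}(a + c)$ on the case indicator (plus optional age/sex
covariates) for abundance, and logistic regression of presence/absence for
prevalence, with a Firth-type bias-reduced fit substituted automatically
when separation occurs. A taxon present in every sample (or absent from
all) is flagged not estimable in prevalence mode and excluded from
pooling. Per-cohort effects are pooled across studies by
DerSimonian-Laird random-effects meta-analysis — the conventional default
moment estimator — and Benjamini-Hochberg correction is applied within
each (disease, mode) family, at an FDR threshold of 0.1. Abundance and
prevalence modes are pooled and reported separately. Cross-disease
classification then labels each taxon consistently health-enriched,
consistently disease-enriched, or context-dependent by the sign agreement
of its significant pooled effects.

## The classification framework

Model evaluation uses 10-times-repeated 5-fold nested cross-validation:
the outer loop measures performance, the inner 5-fold loop — run on the
outer-training portion only — ranks features by univariate AUROC, picks
top-$k$ over the grid $\{16, 32, 64, 128, \text{all}\}$ by inner-CV
AUROC, and tunes hyperparameters by random search at a fixed budget
(default 30 evaluations). Random search at an equal budget was chosen over
sequential model-based optimization: the optimizer's internals are not
what the framework is testing, random search is trivially reproducible
under a seed, and at budgets of this size the difference is noise. The
strict contract is that no statistic computed on held-out samples ever
influences selection; the central correctness property (asserted in the
acceptance suite) is that on pure-noise features the nested AUROC stays at
chance while a deliberately leaky variant — feature selection before
cross-validation — scores far above it.

Five model families are supported: logistic regression, lasso-regularized
logistic regression, elastic net, random forests, and gradient-boosted
trees with the conventional ranges (depth 4-12, learning rate 0.01-0.3,
100-1000 iterations, L2 leaf regularization 1-20). Feature importance is
family-specific: absolute coefficients for the linear models, mean
decrease in impurity for forests, and split gain (a
prediction-value-change analogue) for boosting.

For diseases pooled from three or more cohorts, leave-one-cohort-out CV
replaces the outer loop: each outer iteration holds out one whole study,
so every sample's probability comes from a model that never saw its
cohort — the honest measure of cross-population generalization. Outer
folds are always class-stratified (every fold's class ratio within one
sample of the global ratio); inner folds additionally spread cohorts
across folds.

The final model is fit on all data using the consensus feature set
(features selected in at least half the outer folds — the aggregation is
otherwise arbitrary, and a threshold argument exposes it), with
hyperparameters tuned by 5-fold CV on the full data (the reported tuning
AUROC), and its resubstitution AUROC is labeled optimistic wherever it is
printed. Three further evaluations probe the final model: cross-study
generalization (each single-study model scored on every other study, own
nested AUROC on the diagonal), robustness on external cohorts, and
cross-disease specificity (a good disease model should be near chance on
diseases it never saw). Features absent at prediction time are imputed as
zero — absence of a species is a meaningful zero in relative-abundance
data — with a logged message.

## The MGBA-HI health index

The index is the predicted disease probability reflected around the
Youden-optimal decision threshold:
$\mathrm{MGBA\text{-}HI} = t^\* - \hat p$, where $t^\*$ maximizes
$J(t) = \text{sensitivity}(t) + \text{specificity}(t) - 1$ over all
candidate cuts (midpoints between adjacent sorted unique probabilities,
with ties in $J$ broken toward higher sensitivity — the screening-oriented
choice). Zero marks the decision boundary, positive values a healthy-like
profile. For training-population samples the probabilities are the
out-of-cohort LOCO predictions, never resubstitution — the refit
alternative is available behind the `final_model` argument but is
optimistically biased. Index evaluation reports the two-sided Wilcoxon
rank-sum test, Cliff's delta with the disease-vs-health sign convention
(negative = lower in patients), and Spearman correlations against
phenotypes with percentile-bootstrap confidence intervals (10,000
resamples by default; the percentile method is the simplest defensible
choice for a rank correlation).

## Core protective taxa

Three independent evidence lines intersect: (i) taxa consistently
health-enriched in the pooled differential analysis at FDR < 0.1; (ii)
taxa the index's classifier relies on in the healthy direction, where
direction is estimated by single-feature perturbation (raising the taxon
from its 10th to its 90th training percentile must lower the mean
predicted disease probability); (iii) taxa present at the detection limit
in at least 50% of healthy individuals, pooled across cohorts (a
per-cohort variant is available). The consensus is the set with all three
flags, importance-ordered. Tightening any single criterion can only shrink
the consensus.

## The synthetic-cohort generator

Because the analyses need ground truth, the generator plants a known
structure: per taxon a baseline log2 mean (normal, sd 2) and a structural
absence probability (uniform on 0-0.7); per study a multiplicative batch
bias (log2-normal, sd 0.5 by default) — matching the additive-on-logs
model the corrector targets; per sample a latent log2 abundance (baseline
+ batch bias + case-status effect + noise, sd 1), a zero-inflation mask,
exponentiation, and closure to fractions summing to
$1 - \text{unclassified fraction}$. Ten of 200 taxa carry a planted
disease effect of 1 log2 unit by default; five of them are "protective" —
case-depleted, near-universal in controls (zero-inflation capped at
0.05), elevated baseline — so that the core-taxa consensus has a target.
Metadata (age, sex, BMI, read count from a log-normal around 30 M reads,
unclassified fraction from a Beta with mean 0.12, a `severity` phenotype
shifted in cases) is drawn from fixed distributions, with configurable
fractions of low-read and high-BMI samples to exercise the QC filters.
One global seed expands into per-study substreams, so adding a study never
perturbs existing ones. The default design — three cohorts of 50 cases and
50 controls — is the size at which a multi-cohort case-control
meta-analysis becomes meaningful while staying desk-computable.

What the generator does *not* emulate: real taxon-taxon correlation
structure, phylogenetic signal, country- or platform-level stratification
beyond the study bias, sequencing noise at the read level, and real
MetaPhlAn naming. Passing tests therefore demonstrate the *machinery* —
leakage-safety, calibration, error control, recovery of planted structure
under compositional closure — not biological performance on real cohorts.

## Numerical choices and known limitations

* Pseudocount $5\times10^{-5}$ (half the detection limit) before all
  log10 transforms; results for rare taxa depend on it, as in any
  log-transformed compositional analysis.
* PERMANOVA p-values are permutation-exact up to Monte-Carlo error and
  never below $1/(B+1)$.
* The EB corrector floors within-batch variances at $10^{-8}$ and passes
  constant taxa through untouched.
* AUROC is the midrank (Mann-Whitney) estimator; ties count half.
* Planted-effect recovery is evaluated against the planted taxon set.
  Under strong planted effects on abundant taxa, closure induces genuine
  systematic shifts in *non-planted* taxa, which the differential
  analysis correctly detects; the realized false-discovery proportion
  against the planted list can therefore exceed the BH level even though
  FDR control holds on null data. This is a property of compositional
  data, not of the estimator.
* Problem sizes used by the validation suite (chosen as the smallest
  designs at which the properties are meaningful): 100 samples x 500
  noise features for the leakage check; 3 cohorts x (50+50) samples x
  200 taxa for recovery, batch-correction, index and core-taxa checks;
  999 permutations for reported PERMANOVAs (fewer inside loops); 200
  replicates for null-uniformity calibration.
* Multi-factor PERMANOVA, phylogeny-aware dissimilarities, multi-class
  classification, and pathway-level annotation of the consensus taxa are
  out of scope.
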