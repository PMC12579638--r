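---
title: "Interactome signatures of immunotherapy response: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interactome signatures of immunotherapy response: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrnet)
```

# The analysis problem

A tumor biopsy profiled by single-cell RNA-seq can be summarized as a
directed cell-cell communication network: each directed pair of cell types
(sender, receiver) is connected by the ligand-receptor (LR) interactions
inferred between them. Consensus inference frameworks score each candidate
interaction with several methods, rank the interactions within each method
(rank 1 = strongest evidence), and report two per-interaction summaries per
biopsy: the **mean rank** (arithmetic mean of the per-method ranks, smaller
= stronger) and an **aggregate rank** in (0, 1] that behaves like a p-value
proxy (interactions with aggregate rank ≤ 0.1 are treated as detected).

`lrnet` takes these per-biopsy interaction tables — plus sample metadata
(responder R / non-responder NR, pre/post treatment) — and asks which
interactions, as a multivariate signature, separate the patient groups, and
whether the corresponding genes stratify survival in independent bulk
expression cohorts. A feature is always the full directed key
`sender|receiver|ligand|receptor`, so the same LR pair between different
cell types is a distinct feature.

# Stages and their assumptions

## Interaction frequencies

For each sample, the detected interactions (aggregate rank ≤ 0.1, boundary
inclusive) are counted per directed cell-type pair and divided by the
sample's total detected count, so the frequencies of a sample sum to 1 and
describe *where* the communication diversity sits, ignoring strength.
Samples with no detected interaction get an all-zero row; pairs with no
interaction get frequency 0; self-pairs (B cell to B cell) are valid pairs.
The denominator is the count of *detected* (filtered) interactions, since
the filter is applied before any counting; `filter_significant()` exposes
the cutoff so the unfiltered alternative is one argument away. Group
contrasts use per-pair two-sided Wilcoxon rank-sum tests and the heatmap
statistic `log2((median_A + 0.001) / (median_B + 0.001))` — the 0.001
pseudocount makes the all-zero case well-defined (and exactly 0).

## Missingness thresholding and imputation

Dropout in single-cell data propagates into the interaction tables, so the
sample-by-interaction mean-rank matrix has missing cells wherever an
interaction was not inferred for a sample. Discriminant modeling needs a
complete matrix; the package therefore (1) filters interactions by
completeness and (2) imputes the rest, choosing both knobs by a masking
benchmark: restrict to the columns observed in every sample, mask the same
fraction of cells that is missing in the thresholded matrix, impute, and
score the masked cells by **NRMSE** — RMSE divided by the population
(n-denominator) standard deviation of the true masked values. With the
population denominator, predicting the mean of the masked truth gives
NRMSE exactly 1, which makes 1 an interpretable "no better than a mean
guess" anchor; the sample-sd alternative is a one-line change but loses
the identity.

The threshold is swept coarsely (0 to 1 by 0.1) and then finely (±0.05 by
0.01 around the best coarse point, clipped to [0, 1]); the threshold with
the lowest NRMSE wins, ties toward the smaller threshold because it
retains more features. Grid points where the benchmark is undefined (no
missing cells after filtering, no complete column to mask, or a mask that
rounds to zero cells) are recorded as not evaluable and excluded.

Three imputers are registered. The default is iterative random-forest
imputation run with interactions as rows (samples as columns): initialize
missing cells at column means, then repeatedly re-fit a random forest per
incomplete column (ascending missingness order) until the sum of squared
changes in the imputed cells increases, returning the last non-worsening
state, with at most 20 iterations, 500 trees, `mtry = floor(sqrt(p))` and
seed 123 by default. This is the standard iterative scheme; the stopping
rule is a convention, not a claimed bit-exact reproduction of any
particular implementation. The alternatives are distance-weighted k-nearest
neighbours (Euclidean distance over mutually observed columns, scaled by
the number of shared columns so distances are comparable) and the column
mean. Imputation never alters an observed cell.

## Stability selection

Imputed mean ranks are log10-transformed and fed to repeated
L1-penalized logistic regression (`glmnet`): `n_repeats` fits (default
500), each choosing its penalty by internal stratified 5-fold
cross-validation with a re-randomized fold partition, and recording the
features with non-zero coefficients. Features selected in at least 90% of
repeats are retained. The mixing parameter defaults to `alpha = 1` (pure
LASSO, maximal feature reduction); features are standardized inside each
fit so the penalty treats them comparably.

Two conventions deserve emphasis because the underlying procedure is often
described without them:

* **What varies across repeats** is the internal CV partition (and hence
  the selected penalty), not the data. Subsampling or bootstrapping the
  samples per repeat is the textbook alternative; on cohorts of this size
  (tens of samples) we found it makes redundant true signals — several
  interactions carrying the same group contrast — individually unstable,
  because each repeat can satisfy itself with a different member of the
  redundant set. With the data fixed, a feature's selection is driven by
  whether the penalty path keeps it, which is what the retention frequency
  is meant to measure here.
* **The penalty within each repeat** defaults to the 1-SE rule (largest
  penalty within one standard error of the minimum CV deviance) rather
  than the minimum-deviance penalty. The minimum-deviance rule admits more
  features per repeat, and in null experiments (labels independent of the
  features) it lets spurious features — which on a fixed small cohort can
  correlate substantially with the labels by chance — through to the
  retained set noticeably more often. The 1-SE rule keeps the same planted
  true features at the 90% retention level in our synthetic experiments
  while returning an empty retained set on the large majority of null
  cohorts. `rule = "min"` restores the aggressive variant. A residual
  caveat is inherent to any fixed-data scheme: a chance dataset-level
  correlation is present in every repeat, so no amount of fold
  re-randomization can vote it away; the permutation test downstream is
  the guard against interpreting such signatures.

The biological-plausibility pruning loop (`prune_and_rerun()`) takes a
machine-readable exclusion list (feature id + reason code: intracellular
complex subunit, intracellular localization, refuted interaction), drops
any excluded feature that reaches the retained set, reruns the selection,
and logs each iteration. The judgment of what is implausible is expert
input by design; the package never infers it.

## Two-stage OPLS-DA

The retained features enter an orthogonalized PLS discriminant analysis:
features centered and unit-variance scaled, labels encoded ±1 and
centered, `n_orthogonal` components (default 1, giving the conventional
two-dimensional score plot) capturing label-orthogonal variation removed
by orthogonal signal correction, and one predictive PLS component fitted
on the deflated matrix. By construction the orthogonal scores have exactly
zero correlation with the labels and the predictive scores are orthogonal
to them. A new sample is assigned the class whose training score mean is
nearer its projected score.

Feature influence is measured by VIP (variable importance in projection)
over the predictive component; the squared VIPs average to 1, so VIP > 1
marks above-average contributors. The two-stage fit refits the model on
the VIP > 1 features only, shrinking the signature and reducing
overfitting relative to the sample size. Model quality is the stratified
fivefold cross-validated accuracy (stratification matters: unstratified
folds on a 9-vs-10 cohort can lose a class entirely), and significance is
an empirical permutation p-value: the CV accuracy is recomputed on
`n_permutations` (default 1000) label-shuffled copies, and

\[ p = \max(k, 1) / N, \]

where \(k\) counts null models performing **at least as well** as the
observed one (ties count against the model) and the floor at \(1/N\)
handles the zero-exceedance case. This convention — rather than the
add-one \((k+1)/(N+1)\) variant — is the one consistent with reporting
\(p = 0.011\) for a model beating 989 of 1000 nulls and \(p = 0.001\) for
a model beating all 1000.

## Co-correlate network

Interactions discarded by the completeness threshold re-enter here: each
retained (center) feature is correlated (Pearson) against every other
interaction column of the *unimputed* matrix using pairwise-complete
samples, so the network is tolerant of missing values and unbiased by
imputation. Edges need at least `min_overlap = 5` common samples (Pearson
on fewer points is unstable; the choice is ours). Per center, the five
partners with the largest \(|r|\) — positive or negative alike — are kept,
ties broken lexicographically for determinism, and the network is written
as GraphML plus node/edge TSVs. Functional category labels for nodes are
user-supplied annotations, never computed.

## Survival stratification

For an external cohort with per-patient z-scored bulk expression, the LR
score of an interaction pair is the mean of the z-scores of all its ligand
and receptor genes (cell type deliberately ignored — bulk data have no
cell-type resolution). Patients are clustered on these scores by Ward
agglomeration on Euclidean distances (default `k = 3`, mirroring the
low / high / mixed phenotype structure such cohorts show), with clusters
renumbered by ascending mean score so "cluster 1 = low expression" is
stable across runs. The headline contrast compares the lowest- and
highest-scoring clusters by Kaplan-Meier curves with a log-rank test, and
by a Cox proportional-hazards fit on the cluster indicator after
administrative censoring at 60 months — the most direct reading of a
"5-year hazard ratio". The hazard ratio is reported with its Wald 95% CI
and no derived "percent risk reduction" claim, since HR and CI are the
well-defined quantities.

# The synthetic-data generator

Every stage is validated against simulated cohorts with known ground
truth, because the real discovery cohorts cannot ship with a package. The
generator (`simulate_interaction_cohort()`) emulates the *structure* of
consensus inference output, not its biology:

* per-feature baseline mean ranks drawn from a heavy-tailed (log-normal,
  clipped) distribution over `[1, n_lr_pairs]`, echoing the "small rank =
  strong evidence" semantics with realistic spread;
* five per-method ranks = latent rank + independent Gaussian jitter
  (`method_noise_sd`), averaged into the mean rank;
* an aggregate rank equal to the latent rank mapped into (0, 1] with
  bounded multiplicative noise — monotone in the latent rank, which is the
  only property downstream code relies on;
* planted discriminative features (drawn mid-range so clipping cannot
  flatten them) displaced by `rank_shift` toward smaller ranks in the
  responder group;
* whole-row dropout at `missing_rate` (optionally group-dependent), since
  the downstream matrix has one mean-rank cell per (sample, interaction);
* cell-type pair assignment round-robin over all directed pairs, so
  frequency code exercises every pair.

The default resource size is 4701 features, matching the consensus LR
resource the inference framework draws on; tests use smaller resources
(60-300 features) purely as a problem-size choice. What the generator does
**not** emulate: correlated method errors, feature-feature correlation
structure beyond the planted group effect, compositional coupling between
interactions of one sample, or any biology of specific ligand-receptor
pairs. Passing tests therefore demonstrate that the machinery recovers
planted structure under honest noise and dropout — not that the biological
conclusions drawn from any real cohort are correct.

`simulate_survival_cohort()` plants two expression programs (±1 before
per-gene standardization) and exponential event times with a specified
cluster hazard ratio (baseline median survival 40 months in the
better-off cluster) under independent uniform censoring tuned to an
approximate censoring fraction.

# Numerical choices and degenerate inputs

* Mean ranks average over the methods *present* when a method's rank is
  missing; a row with no method rank is an error.
* `interaction_score = 1 / ln(mean rank)` is only defined for mean rank
  > 1 and errors otherwise; because it is strictly monotone, rank-sum
  tests on scores and on mean ranks give identical p-values (tested).
* Wilcoxon p-values use exact enumeration of the permutation null for
  small samples (up to 200,000 assignments), which handles ties exactly —
  identical groups give p = 1 — and the tie-corrected normal approximation
  beyond that.
* Dunn's post hoc z-tests use the standard tie-corrected pooled variance;
  the multiplicity adjustment defaults to Holm (FWER control without
  Bonferroni's conservatism) and is configurable.
* Ties in the NRMSE sweep go to the smaller threshold; ties in top-k edge
  selection go to the lexicographically smaller partner; Ward cluster
  labels are tied to mean scores — every tie-break is deterministic.
* Collinear (even duplicated) feature columns are accepted everywhere;
  constant features are an error in OPLS-DA (they carry no scaled signal).
* One global pipeline seed derives all per-stage seeds additively, so a
  single integer reproduces a full run; the manifest records input and
  output checksums.

# Problem sizes used by the test-suite experiments

The package's own validation experiments run at deliberately desk-sized
scales: planted-recovery and null-selection experiments use 20 samples per
group, 300-feature resources, 100 selection repeats, and 10 or 40
generator seeds; permutation-calibration uses 50 null datasets with 200
permutations each; survival recovery uses 20 replicates of 400-patient
cohorts. These sizes were chosen to give stable pass/fail behavior for
the properties under test while remaining quick to re-run.

# Known limitations

* The penalty-rule trade-off above is fundamental at these sample sizes:
  retention frequencies cannot distinguish a true signal from a chance
  dataset-level correlation of equal strength. Interpret retained sets
  together with the permutation p-value.
* NRMSE benchmarks masked *complete* columns, which are the least sparse
  and possibly least noisy; the estimated imputability of the thresholded
  matrix is optimistic to that extent (a property of the masking design,
  shared with the reference procedure).
* The OPLS-DA implementation fits one predictive component (the two-class
  case needs no more); multi-class discrimination is out of scope.
* Cross-validated accuracies and permutation p-values obtained on real
  cohorts depend on the upstream inference (which this package does not
  perform); the package reproduces the statistical machinery, not the
  published effect sizes.
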