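# lrnet

Multivariate signatures of immunotherapy response from tumor
ligand–receptor interactomes.

## The problem

Tumor biopsies profiled by single-cell RNA-seq can be summarized as
directed cell–cell communication networks: every directed pair of cell
types is linked by the ligand–receptor (LR) interactions inferred between
them. Consensus inference frameworks rank each candidate interaction with
several methods and report, per biopsy, the interaction's **mean rank**
across methods (smaller = stronger evidence) and an **aggregate rank** in
(0, 1] used as a p-value proxy (≤ 0.1 = detected). `lrnet` turns these
per-biopsy tables into statistics and models that answer three questions:

1. **Where does communication differ?** Per-sample interaction
   frequencies per directed cell-type pair, group contrasts by Wilcoxon
   rank-sum tests, and the heatmap statistic
   `log2((median_A + 0.001) / (median_B + 0.001))`.
2. **Which interactions form a discriminating signature?** A complete
   mean-rank matrix is produced by NRMSE-tuned completeness filtering and
   imputation (iterative random forest / kNN / mean), then repeated
   cross-validated LASSO retains features selected in ≥ 90% of 500 fits,
   a two-stage orthogonalized PLS-DA keeps the VIP > 1 features, and the
   model is scored by stratified fivefold cross-validated accuracy with an
   empirical permutation p-value `p = max(k, 1)/N` (k = label-shuffled
   null models performing at least as well, N permutations). A Pearson
   co-correlate network around the selected features (top 5 partners by
   |r|, pairwise-complete samples) puts the signature in context.
3. **Do the signature genes stratify survival?** Per-patient LR scores
   (mean z-scored expression of each pair's ligand and receptor genes),
   Ward clustering, Kaplan–Meier/log-rank, and a 5-year Cox hazard ratio
   (administrative censoring at 60 months).

A synthetic-data module generates cohorts with planted ground truth
(group-shifted mean ranks, per-method noise, dropout; two-cluster survival
cohorts with a specified hazard ratio) so the whole pipeline is testable
without patient data.

## Worked example

Simulate a cohort of 20 biopsies (10 responders, 10 non-responders) over a
300-interaction resource with 8 planted discriminative interactions, then
run selection and the two-stage discriminant model:

```r
library(lrnet)

cfg <- simulation_config(n_samples_per_group = 10, n_cell_types = 4,
                         n_lr_pairs = 300, n_discriminative = 8,
                         rank_shift = 120, method_noise_sd = 60,
                         missing_rate = 0.2, seed = 1)
sim <- simulate_interaction_cohort(cfg)

mat <- build_rank_matrix(sim$tables, sim$metadata)
X <- log10_transform(impute_matrix(missingness_filter(mat, 0.7), "mean"))
sel <- stability_lasso(X, sim$metadata$response, n_repeats = 100, seed = 1)
print(sel)
#> Stability selection: 273 features, 100 repeats (alpha = 1, 5-fold CV)
#>   retained 6 feature(s) at frequency >= 0.90
#>     cell02|cell03|LG0119|RC0119                        1.00
#>     cell02|cell04|LG0248|RC0248                        1.00
#>     cell03|cell02|LG0282|RC0282                        1.00
#>     cell04|cell01|LG0109|RC0109                        1.00
#>     cell04|cell02|LG0286|RC0286                        1.00
#>     cell04|cell03|LG0159|RC0159                        1.00

fit <- two_stage_fit(X[, sel$retained, drop = FALSE],
                     sim$metadata$response,
                     k = 5, n_permutations = 1000, seed = 2)
print(fit$stage2)
#> OPLS-DA model: 3 features, 20 samples, 1 orthogonal component(s)
#>   classes: NR vs R
#>   training accuracy 1.000; 2 feature(s) with VIP > 1
#>   cross-validated accuracy 0.900
#>   permutation p-value 0.001 (1000 permutations)

intersect(sel$retained, sim$truth$discriminative_keys)  # all 6 are planted
```

Reading the output: after dropout and the 70% completeness filter, 273 of
300 interactions remain; six are selected in every one of the 100 repeated
LASSO fits (frequency 1.00) and all six are planted ground truth. The
VIP > 1 stage keeps three of them; the refitted model classifies held-out
samples at 90% accuracy, and none of 1000 label-shuffled models matches
that, so the empirical p-value is at its floor of 1/1000.

`run_pipeline(pipeline_config(...))` chains the stages (frequencies →
imputation → selection/pruning → OPLS-DA → network, plus survival when
inputs are given), writes per-stage TSV/JSON/GraphML artifacts and a
manifest with seeds and checksums; a single global seed makes runs
byte-reproducible. See the methods vignette
(`vignettes/interactome-signatures.Rmd`) for the model details and design
rationale.

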