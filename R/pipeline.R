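#' Pipeline configuration
#'
#' Collects the settings of every stage of the interactome analysis with
#' defaults matching the reference analysis: aggregate-rank cutoff 0.1,
#' coarse-plus-fine NRMSE threshold sweep, LASSO alpha 1 with 500 repeats
#' and 90% retention, VIP cutoff 1, fivefold CV, 1000 permutations, top-5
#' co-correlates, 3 survival clusters, random-forest imputation with 500
#' trees. A single global seed deterministically derives the per-stage
#' seeds.
#'
#' @param output_dir directory for stage artifacts and the manifest.
#' @param interaction_paths,metadata_path,exclusion_path optional input file
#'   paths (interaction tables and metadata may instead be passed in memory
#'   to [run_pipeline()]). The exclusion list is a TSV with columns
#'   `feature_id`, `reason`.
#' @param aggregate_rank_cutoff detection cutoff for the frequency stage.
#' @param alpha,n_repeats,retention stability-selection settings.
#' @param vip_cutoff,cv_folds,n_permutations,n_orthogonal OPLS-DA settings.
#' @param top_k_correlates,min_overlap co-correlate network settings.
#' @param clusters_k survival cluster count.
#' @param imputer,rf_ntree,rf_maxiter imputation settings.
#' @param seed global integer seed (< 2^31 - 16).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            interaction_paths = NULL,
                            metadata_path = NULL,
                            exclusion_path = NULL,
                            aggregate_rank_cutoff = 0.1,
                            alpha = 1,
                            n_repeats = 500L,
                            retention = 0.9,
                            vip_cutoff = 1,
                            cv_folds = 5L,
                            n_permutations = 1000L,
                            n_orthogonal = 1L,
                            top_k_correlates = 5L,
                            min_overlap = 5L,
                            clusters_k = 3L,
                            imputer = "random_forest",
                            rf_ntree = 500L,
                            rf_maxiter = 20L,
                            seed = 123L) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed < 0 || seed > 2^31 - 16)
    stop("invalid 'seed': must be a non-negative integer < 2^31 - 16",
         call. = FALSE)
  cfg <- list(output_dir = output_dir,
              interaction_paths = interaction_paths,
              metadata_path = metadata_path,
              exclusion_path = exclusion_path,
              aggregate_rank_cutoff = aggregate_rank_cutoff,
              alpha = alpha, n_repeats = as.integer(n_repeats),
              retention = retention, vip_cutoff = vip_cutoff,
              cv_folds = as.integer(cv_folds),
              n_permutations = as.integer(n_permutations),
              n_orthogonal = as.integer(n_orthogonal),
              top_k_correlates = as.integer(top_k_correlates),
              min_overlap = as.integer(min_overlap),
              clusters_k = as.integer(clusters_k),
              imputer = match.arg(imputer,
                                  c("random_forest", "knn", "mean")),
              rf_ntree = as.integer(rf_ntree),
              rf_maxiter = as.integer(rf_maxiter),
              seed = as.integer(seed))
  if (cfg$aggregate_rank_cutoff <= 0 || cfg$aggregate_rank_cutoff > 1)
    stop("invalid 'aggregate_rank_cutoff': must be in (0, 1]", call. = FALSE)
  if (cfg$retention < 0 || cfg$retention > 1)
    stop("invalid 'retention': must be in [0, 1]", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

.stage_seed <- function(cfg, stage_index) cfg$seed + stage_index

#' Run the full interactome analysis pipeline
#'
#' Chains the stages: interaction frequencies (filter, per-pair
#' frequencies, group fold changes and Wilcoxon tests), NRMSE threshold
#' sweep and imputation, stability LASSO (with exclusion-list pruning when
#' an exclusion file is configured), two-stage OPLS-DA with cross-validated
#' accuracy and permutation p-value, and the co-correlate network. Writes
#' one artifact set per stage plus a manifest recording input checksums,
#' per-stage seeds, settings and output checksums; two runs with the same
#' config and inputs produce byte-identical numeric artifacts.
#'
#' @param config a [pipeline_config()].
#' @param tables named list of interaction data frames (else read from
#'   `config$interaction_paths`).
#' @param metadata sample metadata data frame (else read from
#'   `config$metadata_path`); needs `sample_id` and `response` columns, and
#'   the response comparison uses the samples labeled `R` or `NR`.
#' @param survival_input optional list with `z` (patient x gene z-scores),
#'   `os_months`, `event`, and `pairs` (as in [lr_scores()]) to run the
#'   survival stage.
#' @return Invisibly, a list with the stage results (`frequencies`,
#'   `imputation`, `selection`, `oplsda`, `network`, optionally `survival`)
#'   and the manifest.
#' @export
run_pipeline <- function(config, tables = NULL, metadata = NULL,
                         survival_input = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)

  if (is.null(tables)) {
    if (is.null(config$interaction_paths))
      stop("no interaction tables given (in memory or via config paths)",
           call. = FALSE)
    tables <- read_interaction_tables(config$interaction_paths)
  }
  if (is.null(metadata)) {
    if (is.null(config$metadata_path))
      stop("no metadata given (in memory or via config path)", call. = FALSE)
    metadata <- read.delim(config$metadata_path, stringsAsFactors = FALSE)
  }
  if (!all(c("sample_id", "response") %in% names(metadata)))
    stop("metadata needs 'sample_id' and 'response' columns", call. = FALSE)

  ## stage 1: interaction frequencies -----------------------------------
  filtered <- lapply(tables, filter_significant,
                     cutoff = config$aggregate_rank_cutoff)
  freq <- pair_frequencies(filtered)
  .write_tsv(data.frame(sample_id = rownames(freq), freq,
                        check.names = FALSE), out("frequencies.tsv"))
  resp <- metadata$response[match(rownames(freq), metadata$sample_id)]
  groups_ok <- all(c("R", "NR") %in% resp)
  freq_stats <- NULL
  if (groups_ok) {
    fc <- median_log2_fc(freq[resp == "R", , drop = FALSE],
                         freq[resp == "NR", , drop = FALSE])
    tests <- compare_pair_frequencies(
      freq[resp %in% c("R", "NR"), , drop = FALSE],
      resp[resp %in% c("R", "NR")])
    tests$log2_fc_R_vs_NR <- fc[tests$pair]
    .write_tsv(tests, out("frequency_tests.tsv"))
    freq_stats <- tests
  }

  ## stage 2: rank matrix, threshold sweep, imputation ------------------
  mat <- build_rank_matrix(tables, metadata)
  comp <- resp %in% c("R", "NR")
  if (!any(comp)) stop("no sample labeled R or NR", call. = FALSE)
  mat_cmp <- mat[comp, , drop = FALSE]
  y <- factor(resp[comp])
  sweep_seed <- .stage_seed(config, 1L)
  report <- threshold_sweep(mat_cmp, imputer = config$imputer,
                            seed = sweep_seed, ntree = config$rf_ntree,
                            maxiter = config$rf_maxiter)
  sub <- missingness_filter(mat_cmp, report$chosen_threshold)
  imputed <- impute_matrix(sub, method = config$imputer,
                           ntree = config$rf_ntree,
                           maxiter = config$rf_maxiter, seed = sweep_seed)
  jsonlite::write_json(
    list(chosen_threshold = report$chosen_threshold,
         chosen_imputer = report$chosen_imputer,
         best_coarse = report$best_coarse, mask_seed = report$mask_seed,
         masked_fraction = report$masked_fraction, grid = report$grid),
    out("imputation_report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  .write_tsv(data.frame(sample_id = rownames(imputed), imputed,
                        check.names = FALSE), out("imputed_matrix.tsv"))

  ## stage 3: stability selection (+ pruning) ---------------------------
  X <- log10_transform(imputed)
  sel_seed <- .stage_seed(config, 2L)
  exclusion <- character(0)
  reasons <- NULL
  if (!is.null(config$exclusion_path)) {
    ex <- read.delim(config$exclusion_path, stringsAsFactors = FALSE)
    exclusion <- ex$feature_id
    reasons <- if ("reason" %in% names(ex)) ex$reason else NULL
  }
  pruned <- prune_and_rerun(X, y, exclusion = exclusion, reasons = reasons,
                            alpha = config$alpha,
                            n_repeats = config$n_repeats,
                            retention = config$retention,
                            nfolds = config$cv_folds, seed = sel_seed)
  sel <- pruned$selection
  .write_tsv(data.frame(feature_id = sel$feature_ids,
                        frequency = sel$frequency,
                        retained = sel$feature_ids %in% sel$retained),
             out("selection.tsv"))
  if (length(sel$retained) == 0L)
    stop("stability selection retained no feature; ",
         "no signature to carry forward", call. = FALSE)

  ## stage 4: two-stage OPLS-DA -----------------------------------------
  fit <- two_stage_fit(X[, sel$retained, drop = FALSE], y,
                       k = config$cv_folds,
                       n_permutations = config$n_permutations,
                       n_orthogonal = config$n_orthogonal,
                       vip_cutoff = config$vip_cutoff,
                       seed = .stage_seed(config, 3L))
  perm <- fit$stage2$permutation
  jsonlite::write_json(
    list(stage1_features = names(vip(fit$stage1)),
         stage1_vip = unname(vip(fit$stage1)),
         stage2_features = fit$features,
         stage2_vip = unname(vip(fit$stage2)),
         cv_accuracy = fit$stage2$cv_accuracy,
         permutation = list(n_permutations = perm$n_permutations,
                            observed_metric = perm$observed_metric,
                            k_at_least = perm$k_at_least,
                            null_mean = mean(perm$null_metrics),
                            p_value = perm$p_value)),
    out("oplsda_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  ## stage 5: co-correlate network --------------------------------------
  enrich <- vapply(sel$retained, function(f) {
    med <- tapply(mat_cmp[, f], y, median, na.rm = TRUE)
    names(which.min(med))             # enriched where ranks are stronger
  }, character(1))
  edges <- pairwise_pearson(sel$retained, mat_cmp,
                            min_overlap = config$min_overlap)
  edges <- top_k_edges(edges, k = config$top_k_correlates)
  graph <- export_network(edges, out("network"), centers = sel$retained,
                          annotations = enrich)

  ## optional stage 6: survival -----------------------------------------
  surv_res <- NULL
  if (!is.null(survival_input)) {
    scores <- lr_scores(survival_input$z, survival_input$pairs)
    cl <- ward_cluster(scores, k = config$clusters_k)
    lo <- 1L
    hi <- max(cl)
    km <- km_logrank(survival_input$os_months, survival_input$event, cl,
                     groups = c(lo, hi))
    cox <- cox_hr_5yr(survival_input$os_months, survival_input$event, cl,
                      reference = hi, comparison = lo)
    surv_res <- list(cluster_sizes = as.list(table(cl)),
                     logrank_p = km$p_value, hr = cox$hr,
                     ci_lower = cox$ci_lower, ci_upper = cox$ci_upper)
    jsonlite::write_json(surv_res, out("survival_results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    surv_res$clusters <- cl
  }

  ## manifest -------------------------------------------------------------
  input_paths <- c(config$interaction_paths, config$metadata_path,
                   config$exclusion_path)
  outputs <- list.files(config$output_dir, full.names = TRUE)
  outputs <- setdiff(outputs, out("manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("lrnet")),
    settings = config[setdiff(names(config),
                              c("interaction_paths", "metadata_path",
                                "exclusion_path", "output_dir"))],
    stage_seeds = list(imputation = sweep_seed, selection = sel_seed,
                       oplsda = .stage_seed(config, 3L)),
    inputs = if (length(input_paths))
      as.list(tools::md5sum(input_paths)) else list(),
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(frequencies = freq, frequency_tests = freq_stats,
                 imputation = report, imputed = imputed, selection = sel,
                 pruning = pruned$pruning, oplsda = fit, network = graph,
                 edges = edges, survival = surv_res, manifest = manifest))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
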