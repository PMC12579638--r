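#' Configuration for the synthetic interaction-cohort generator
#'
#' Bundles and validates the parameters of [simulate_interaction_cohort()].
#' The generator emulates consensus LR inference output: for every biopsy, a
#' table of directed ligand-receptor interactions carrying one rank per
#' inference method, an aggregate rank in (0, 1] that behaves like a p-value
#' proxy, and the per-interaction mean rank. A configurable subset of
#' "planted" interactions has its mean rank shifted toward stronger evidence
#' (smaller rank) in the responder group, giving every downstream stage a
#' known ground truth.
#'
#' @param n_samples_per_group samples per response group (R and NR).
#' @param n_cell_types number of cell types; interactions are assigned
#'   round-robin over all directed (sender, receiver) pairs including
#'   self-pairs.
#' @param n_lr_pairs size of the LR resource (default 4701, the size of the
#'   consensus resource used for inference).
#' @param n_discriminative number of planted discriminative interactions.
#' @param rank_shift mean-rank displacement of planted interactions between
#'   groups (smaller = stronger in responders).
#' @param method_noise_sd standard deviation of the per-method rank jitter
#'   around the latent rank.
#' @param missing_rate fraction of interaction rows dropped per sample.
#' @param group_missing_delta extra dropout applied to the NR group, so that
#'   missingness can be group-dependent.
#' @param seed integer seed; identical seeds give identical cohorts.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [simulate_interaction_cohort()]
#' @export
simulation_config <- function(n_samples_per_group = 10,
                              n_cell_types = 5,
                              n_lr_pairs = 4701,
                              n_discriminative = 10,
                              rank_shift = 800,
                              method_noise_sd = 300,
                              missing_rate = 0.3,
                              group_missing_delta = 0,
                              seed = 1L) {
  cfg <- list(n_samples_per_group = as.integer(n_samples_per_group),
              n_cell_types = as.integer(n_cell_types),
              n_lr_pairs = as.integer(n_lr_pairs),
              n_discriminative = as.integer(n_discriminative),
              rank_shift = as.numeric(rank_shift),
              method_noise_sd = as.numeric(method_noise_sd),
              missing_rate = as.numeric(missing_rate),
              group_missing_delta = as.numeric(group_missing_delta),
              seed = as.integer(seed))
  counts <- c("n_samples_per_group", "n_cell_types", "n_lr_pairs")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("'", nm, "' must be a count >= 1", call. = FALSE)
  }
  if (cfg$n_discriminative < 0L || cfg$n_discriminative > cfg$n_lr_pairs)
    stop("'n_discriminative' must be in [0, n_lr_pairs]", call. = FALSE)
  if (cfg$rank_shift < 0)
    stop("'rank_shift' must be non-negative", call. = FALSE)
  if (cfg$method_noise_sd < 0)
    stop("'method_noise_sd' must be non-negative", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("'missing_rate' must be a fraction in [0, 1)", call. = FALSE)
  if (cfg$missing_rate + abs(cfg$group_missing_delta) >= 1)
    stop("missing_rate + |group_missing_delta| must be < 1", call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic interaction cohort configuration\n")
  cat(sprintf("  %d samples/group, %d cell types, %d LR pairs\n",
              x$n_samples_per_group, x$n_cell_types, x$n_lr_pairs))
  cat(sprintf("  %d planted features, rank shift %.1f, method noise sd %.1f\n",
              x$n_discriminative, x$rank_shift, x$method_noise_sd))
  cat(sprintf("  dropout %.2f (+%.2f in NR), seed %d\n",
              x$missing_rate, x$group_missing_delta, x$seed))
  invisible(x)
}

.lr_methods <- c("natmi", "connectome", "logfc", "sca", "cellphonedb")

#' Simulate a cohort of per-sample ligand-receptor interaction tables
#'
#' Generates one ranked interaction table per biopsy plus sample metadata and
#' a ground-truth record. Each interaction has a latent per-sample rank drawn
#' around a heavy-tailed per-feature baseline on `[1, n_lr_pairs]`; the five
#' per-method ranks are the latent rank plus independent Gaussian jitter, the
#' mean rank is their average, and the aggregate rank is the latent rank
#' mapped into (0, 1] with bounded multiplicative noise (so it is monotone in
#' the latent rank, as a p-value proxy should be). Planted discriminative
#' interactions are displaced by `rank_shift` toward smaller (stronger) ranks
#' in the responder group. Dropout removes whole interaction rows at the
#' configured per-group rate.
#'
#' @param config a [simulation_config()].
#' @return A list with elements:
#' \describe{
#'   \item{tables}{named list (by sample id) of interaction data frames in
#'     the format read by [read_interaction_tables()].}
#'   \item{metadata}{data frame with `sample_id`, `patient_id`, `timepoint`,
#'     `response`.}
#'   \item{truth}{list with `discriminative_keys` (feature ids of planted
#'     interactions), `group_of_sample`, and the generating parameters.}
#' }
#' @export
simulate_interaction_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("'config' must be a simulation_config object", call. = FALSE)
  set.seed(config$seed)
  n  <- config$n_lr_pairs
  ct <- sprintf("cell%02d", seq_len(config$n_cell_types))
  pairs <- expand.grid(receiver = ct, sender = ct,
                       stringsAsFactors = FALSE)[, c("sender", "receiver")]
  idx <- ((seq_len(n) - 1L) %% nrow(pairs)) + 1L
  features <- data.frame(
    source = pairs$sender[idx],
    target = pairs$receiver[idx],
    ligand_complex = sprintf("LG%04d", seq_len(n)),
    receptor_complex = sprintf("RC%04d", seq_len(n)),
    stringsAsFactors = FALSE)
  features$feature_id <- make_feature_id(features$source, features$target,
                                         features$ligand_complex,
                                         features$receptor_complex)

  # heavy-tailed baseline ranks; planted features sit mid-range so the group
  # shift is not flattened by clipping at the rank boundaries
  baseline <- pmin(pmax(exp(rnorm(n, mean = log(n / 4), sd = 1)), 1), n)
  planted <- if (config$n_discriminative > 0L)
    sort(sample.int(n, config$n_discriminative)) else integer(0)
  if (length(planted))
    baseline[planted] <- runif(length(planted), 0.35, 0.65) * n

  n_g <- config$n_samples_per_group
  sample_ids <- sprintf("S%02d", seq_len(2L * n_g))
  groups <- rep(c("R", "NR"), each = n_g)
  drop_rate <- ifelse(groups == "R", config$missing_rate,
                      config$missing_rate + config$group_missing_delta)
  drop_rate <- pmin(pmax(drop_rate, 0), 1 - 1e-9)

  tables <- vector("list", length(sample_ids))
  names(tables) <- sample_ids
  for (s in seq_along(sample_ids)) {
    shift <- numeric(n)
    if (length(planted))
      shift[planted] <- if (groups[s] == "R") -config$rank_shift / 2 else
        config$rank_shift / 2
    latent <- pmin(pmax(baseline + shift, 1), n)
    meth <- matrix(rnorm(n * 5L, sd = config$method_noise_sd), n, 5L)
    meth <- pmin(pmax(latent + meth, 1), n)
    colnames(meth) <- paste0(.lr_methods, "_rank")
    agg_noise <- exp(pmin(pmax(rnorm(n, sd = 0.1), -0.25), 0.25))
    agg <- pmin(pmax(latent / n * agg_noise, 1e-6), 1)
    tab <- cbind(data.frame(sample_id = sample_ids[s],
                            stringsAsFactors = FALSE),
                 features[, c("source", "target", "ligand_complex",
                              "receptor_complex")],
                 as.data.frame(meth),
                 data.frame(aggregate_rank = agg))
    tab$mean_rank <- rowMeans(meth)
    tab$feature_id <- features$feature_id
    n_drop <- round(drop_rate[s] * n)
    if (n_drop > 0L) {
      keep <- sort(sample.int(n, n - n_drop))
      tab <- tab[keep, , drop = FALSE]
    }
    rownames(tab) <- NULL
    tables[[s]] <- tab
  }

  metadata <- data.frame(sample_id = sample_ids,
                         patient_id = sprintf("P%02d", seq_along(sample_ids)),
                         timepoint = "pre",
                         response = groups,
                         stringsAsFactors = FALSE)
  truth <- list(discriminative_keys = features$feature_id[planted],
                group_of_sample = stats::setNames(groups, sample_ids),
                rank_shift = config$rank_shift,
                seed = config$seed)
  list(tables = tables, metadata = metadata, truth = truth)
}

#' Simulate a two-cluster survival cohort with z-scored expression
#'
#' Emulates the survival-validation input: a patient-by-gene table of
#' z-scored bulk expression in which two latent patient clusters carry
#' distinct mean expression programs, with exponential overall-survival times
#' whose cluster-specific hazards have the requested ratio and independent
#' uniform censoring. Cluster 1 is the low-expression, higher-hazard group.
#'
#' @param n_patients number of patients (>= 2); split evenly into the two
#'   clusters.
#' @param genes character vector of gene symbols (non-empty).
#' @param hazard_ratio hazard of cluster 1 relative to cluster 2 (> 0).
#' @param censor_rate approximate fraction of censored patients in `[0, 1)`.
#' @param seed integer seed.
#' @param program_effect half-distance between cluster mean expression
#'   programs, in pre-standardization units (default 1).
#'
#' @return A list with `z` (patient x gene matrix, each gene standardized to
#'   mean 0, sd 1), `os_months`, `event` (1 = death observed), and `truth`
#'   (cluster labels and the generating hazard ratio).
#' @export
simulate_survival_cohort <- function(n_patients, genes, hazard_ratio,
                                     censor_rate = 0.2, seed = 1L,
                                     program_effect = 1) {
  if (n_patients < 2) stop("'n_patients' must be >= 2", call. = FALSE)
  if (length(genes) == 0) stop("'genes' must be non-empty", call. = FALSE)
  if (hazard_ratio <= 0) stop("'hazard_ratio' must be > 0", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("'censor_rate' must be in [0, 1)", call. = FALSE)
  set.seed(as.integer(seed))
  cluster <- rep(c(1L, 2L), length.out = n_patients)
  mu <- ifelse(cluster == 1L, -program_effect, program_effect)
  z <- matrix(rnorm(n_patients * length(genes)), n_patients, length(genes)) + mu
  z <- scale(z)                       # per-gene mean 0, sd 1
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  dimnames(z) <- list(sprintf("PT%03d", seq_len(n_patients)), toupper(genes))

  lambda2 <- log(2) / 40              # median OS ~40 months in the better group
  lambda <- ifelse(cluster == 1L, lambda2 * hazard_ratio, lambda2)
  t_event <- rexp(n_patients, rate = lambda)
  if (censor_rate > 0) {
    c_max <- mean(1 / lambda) / censor_rate
    t_cens <- runif(n_patients, 0, c_max)
  } else {
    t_cens <- rep(Inf, n_patients)
  }
  os <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  list(z = z,
       os_months = stats::setNames(os, rownames(z)),
       event = stats::setNames(event, rownames(z)),
       truth = list(cluster = stats::setNames(cluster, rownames(z)),
                    hazard_ratio = hazard_ratio, seed = as.integer(seed)))
}
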