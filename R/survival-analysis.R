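#' Ligand-receptor expression scores per patient
#'
#' The LR score of an interaction pair for a patient is the arithmetic mean
#' of the z-scored expression of all ligand and receptor genes of the pair;
#' cell-type identity is not considered. Gene symbols are matched exactly
#' after uppercasing; genes absent from the expression table are dropped
#' from the mean with a warning, and a pair with no measurable gene is an
#' error.
#'
#' @param z patient-by-gene matrix of z-scored expression (column names =
#'   gene symbols).
#' @param pairs named list of pairs, each a list with character elements
#'   `ligand` and `receptor` (complexes allowed: several genes).
#' @return Patient-by-pair matrix of LR scores.
#' @export
lr_scores <- function(z, pairs) {
  z <- as.matrix(z)
  colnames(z) <- toupper(colnames(z))
  if (length(pairs) == 0L) stop("'pairs' must be non-empty", call. = FALSE)
  ids <- names(pairs)
  if (is.null(ids))
    ids <- vapply(pairs, function(p)
      paste(paste(p$ligand, collapse = "_"),
            paste(p$receptor, collapse = "_"), sep = "->"), character(1))
  scores <- matrix(NA_real_, nrow(z), length(pairs),
                   dimnames = list(rownames(z), ids))
  for (i in seq_along(pairs)) {
    genes <- unique(toupper(c(pairs[[i]]$ligand, pairs[[i]]$receptor)))
    present <- intersect(genes, colnames(z))
    absent <- setdiff(genes, colnames(z))
    if (length(present) == 0L)
      stop("pair '", ids[i], "': no constituent gene in the expression table",
           call. = FALSE)
    if (length(absent))
      warning("pair '", ids[i], "': dropping unmeasured gene(s) ",
              paste(absent, collapse = ", "))
    scores[, i] <- rowMeans(z[, present, drop = FALSE])
  }
  scores
}

#' Ward clustering of patients on LR scores
#'
#' Agglomerative clustering with Ward linkage on Euclidean distances over
#' the LR score columns, cut at `k` clusters. Cluster labels are renumbered
#' by ascending mean score, so cluster 1 is the low-expression group and
#' cluster `k` the high-expression group, independent of input order.
#'
#' @param scores patient-by-pair score matrix with no missing values.
#' @param k number of clusters (default 3).
#' @return Named integer vector of cluster labels (1 = lowest mean score).
#' @export
ward_cluster <- function(scores, k = 3L) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("scores must be complete", call. = FALSE)
  if (k > nrow(scores)) stop("k exceeds the number of patients", call. = FALSE)
  if (k == 1L)
    return(stats::setNames(rep(1L, nrow(scores)), rownames(scores)))
  hc <- hclust(dist(scores), method = "ward.D2")
  raw <- cutree(hc, k = k)
  mean_score <- tapply(rowMeans(scores), raw, mean)
  relabel <- stats::setNames(rank(mean_score, ties.method = "first"),
                             names(mean_score))
  out <- as.integer(relabel[as.character(raw)])
  names(out) <- rownames(scores)
  out
}

#' Kaplan-Meier curves and log-rank test between two patient groups
#'
#' @param time follow-up times (e.g. overall survival in months).
#' @param event event indicator (1 = death observed, 0 = censored).
#' @param group group label per patient.
#' @param groups optional pair of labels selecting the two groups to
#'   compare; defaults to all (must then be exactly two).
#' @return List with `fit` (the [survival::survfit] Kaplan-Meier object),
#'   `chisq`, `p_value` and per-group sizes.
#' @export
km_logrank <- function(time, event, group, groups = NULL) {
  group <- as.character(group)
  if (!is.null(groups)) {
    keep <- group %in% groups
    time <- time[keep]; event <- event[keep]; group <- group[keep]
  }
  lev <- unique(group)
  if (length(lev) != 2L) stop("exactly two groups are required", call. = FALSE)
  if (any(table(group) == 0L)) stop("both groups must be non-empty",
                                    call. = FALSE)
  if (sum(event) == 0L) stop("no events observed", call. = FALSE)
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chisq <- sd_$chisq
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  list(fit = fit, chisq = chisq, p_value = p,
       n = table(group))
}

#' Five-year Cox hazard ratio between two clusters
#'
#' Administratively censors follow-up at the horizon (60 months), then fits
#' a single binary-covariate Cox proportional hazards model and reports the
#' hazard ratio of the comparison cluster relative to the reference, with
#' the Wald 95% confidence interval.
#'
#' @param time,event,group as in [km_logrank()].
#' @param reference,comparison the two cluster labels; the hazard ratio is
#'   for `comparison` vs `reference`.
#' @param horizon administrative censoring horizon in the time unit of
#'   `time` (default 60 months).
#' @return List with `hr`, `ci_lower`, `ci_upper`, `n`, `events` and the
#'   fitted [survival::coxph] model.
#' @export
cox_hr_5yr <- function(time, event, group, reference, comparison,
                       horizon = 60) {
  group <- as.character(group)
  keep <- group %in% c(reference, comparison)
  time <- time[keep]; event <- event[keep]; group <- group[keep]
  if (!any(group == reference) || !any(group == comparison))
    stop("both clusters must be non-empty", call. = FALSE)
  event <- as.integer(event == 1 & time <= horizon)
  time <- pmin(time, horizon)
  if (sum(event) == 0L)
    stop("no events within the ", horizon, "-month window", call. = FALSE)
  x <- factor(group, levels = c(reference, comparison))
  fit <- survival::coxph(survival::Surv(time, event) ~ x)
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0))
    stop("Cox fit did not converge", call. = FALSE)
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  if (!is.finite(beta) || !is.finite(se))
    stop("Cox fit degenerate (non-finite coefficient)", call. = FALSE)
  list(hr = exp(beta),
       ci_lower = exp(beta - 1.959964 * se),
       ci_upper = exp(beta + 1.959964 * se),
       n = table(x), events = sum(event), model = fit)
}
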