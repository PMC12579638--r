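#' Log10 transform of a complete rank matrix
#'
#' Mean ranks are log10-transformed before penalized modeling so that the
#' heavy right tail of the rank distribution does not dominate the fits.
#'
#' @param mat complete numeric matrix with all values > 0.
#' @return `log10(mat)`.
#' @export
log10_transform <- function(mat) {
  if (anyNA(mat)) stop("matrix must be complete (no NA)", call. = FALSE)
  if (any(mat <= 0)) stop("all values must be > 0", call. = FALSE)
  log10(mat)
}

#' Stability selection by repeated cross-validated LASSO
#'
#' Fits an elastic-net-penalized logistic classification path `n_repeats`
#' times; in each repeat the penalty is chosen by internal stratified k-fold
#' cross-validation whose fold partition is re-randomized, and the features
#' with non-zero coefficients at the selected penalty are recorded. The
#' selection frequency of a feature is the fraction of repeats in which it
#' was selected; features at or above the retention threshold are retained.
#' Features are standardized to unit variance inside each fit so the penalty
#' is comparable across features.
#'
#' @param X complete numeric feature matrix (samples x features).
#' @param y binary labels (two classes, each with at least `nfolds`
#'   samples).
#' @param alpha elastic-net mixing parameter in (0, 1]; 1 = pure LASSO
#'   (the default, chosen for maximal feature reduction).
#' @param n_repeats number of repeated fits (default 500).
#' @param retention selection-frequency threshold for retention
#'   (default 0.9).
#' @param nfolds folds of the internal cross-validation (default 5).
#' @param rule penalty-selection rule within each repeat: `"1se"` (default,
#'   the largest penalty within one standard error of the minimum
#'   cross-validated deviance — conservative, so pure-noise features are
#'   rarely retained) or `"min"` (minimum CV deviance — maximal
#'   sensitivity).
#' @param seed integer seed; results are deterministic given the seed.
#' @return An object of class `stability_selection` with `feature_ids`,
#'   `frequency` (per feature), `retained` (feature ids with frequency >=
#'   `retention`), and the settings.
#' @export
stability_lasso <- function(X, y, alpha = 1, n_repeats = 500L,
                            retention = 0.9, nfolds = 5L,
                            rule = c("1se", "min"), seed = 1L) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]", call. = FALSE)
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly two classes", call. = FALSE)
  if (any(table(y) < nfolds))
    stop("each class needs at least 'nfolds' samples", call. = FALSE)
  features <- colnames(X)
  if (is.null(features)) features <- paste0("V", seq_len(ncol(X)))
  # glmnet requires >= 2 columns; pad single-feature input with a null column
  pad <- ncol(X) == 1L
  Xg <- if (pad) cbind(X, .pad. = 0) else X
  set.seed(as.integer(seed))
  counts <- numeric(ncol(X))
  for (r in seq_len(n_repeats)) {
    foldid <- .stratified_folds(y, nfolds)
    # glmnet warns whenever a class has < 8 members; routine for cohorts
    # of this size, so that specific warning is muffled
    cv <- withCallingHandlers(
      glmnet::cv.glmnet(Xg, y, family = "binomial", alpha = alpha,
                        foldid = foldid, standardize = TRUE,
                        type.measure = "deviance"),
      warning = function(w) {
        if (grepl("fewer than 8\\s+observations|grouped=FALSE",
                  conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    s <- if (rule == "1se") "lambda.1se" else "lambda.min"
    beta <- as.numeric(stats::coef(cv, s = s))[-1]  # drop intercept
    counts <- counts + (beta[seq_len(ncol(X))] != 0)
  }
  freq <- counts / n_repeats
  names(freq) <- features
  out <- list(feature_ids = features, frequency = freq,
              retained = features[freq >= retention], alpha = alpha,
              n_repeats = as.integer(n_repeats), retention = retention,
              nfolds = as.integer(nfolds), rule = rule,
              seed = as.integer(seed))
  class(out) <- "stability_selection"
  out
}

.stratified_folds <- function(y, k) {
  foldid <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    foldid[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  foldid
}

#' @export
print.stability_selection <- function(x, ...) {
  cat(sprintf(
    "Stability selection: %d features, %d repeats (alpha = %g, %d-fold CV)\n",
    length(x$feature_ids), x$n_repeats, x$alpha, x$nfolds))
  cat(sprintf("  retained %d feature(s) at frequency >= %.2f\n",
              length(x$retained), x$retention))
  if (length(x$retained)) {
    top <- sort(x$frequency[x$retained], decreasing = TRUE)
    for (nm in names(head(top, 10L)))
      cat(sprintf("    %-50s %.2f\n", nm, top[[nm]]))
    if (length(top) > 10L) cat("    ...\n")
  }
  invisible(x)
}

#' Iterative pruning of implausible features with re-selection
#'
#' Mirrors the expert-curated pruning loop: run stability selection, check
#' the retained set against a machine-readable exclusion list (e.g.
#' single-cell complex subunits, intracellular molecules, refuted
#' interactions), drop any retained excluded features and rerun, until the
#' retained set contains no excluded feature. Each iteration is logged.
#'
#' @param X,y,... as in [stability_lasso()].
#' @param exclusion character vector of feature ids to exclude; entries not
#'   present in `X` are ignored with a warning.
#' @param reasons optional character vector (same length as `exclusion`) of
#'   reason codes.
#' @return List with `selection` (the final [stability_lasso()] result) and
#'   `pruning`, a list of per-iteration records (`iteration`,
#'   `excluded_features`, `reasons`, `retained_after`).
#' @export
prune_and_rerun <- function(X, y, exclusion = character(0), reasons = NULL,
                            ...) {
  X <- as.matrix(X)
  feats <- colnames(X)
  if (is.null(feats)) stop("X must have column names", call. = FALSE)
  unknown <- setdiff(exclusion, feats)
  if (length(unknown))
    warning("ignoring ", length(unknown),
            " exclusion feature(s) not present in X")
  if (!is.null(reasons)) names(reasons) <- exclusion
  records <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (ncol(X) == 0L)
      stop("all features excluded; nothing left to select", call. = FALSE)
    sel <- stability_lasso(X, y, ...)
    bad <- intersect(sel$retained, exclusion)
    if (length(bad) == 0L) break
    keep <- setdiff(colnames(X), bad)
    records[[iter]] <- list(
      iteration = iter, excluded_features = bad,
      reasons = if (is.null(reasons)) rep(NA_character_, length(bad))
        else unname(reasons[bad]),
      retained_after = setdiff(sel$retained, bad))
    X <- X[, keep, drop = FALSE]
    if (iter > length(feats)) stop("pruning failed to terminate",
                                   call. = FALSE)   # unreachable guard
  }
  list(selection = sel, pruning = records)
}
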