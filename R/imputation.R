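#' Filter interactions by completeness across samples
#'
#' Keeps interaction columns whose fraction of present (non-missing) values
#' across samples is at least `tau`; the boundary is inclusive, so with ten
#' samples and `tau = 0.7` a column observed in exactly seven samples
#' survives.
#'
#' @param mat sample-by-interaction mean-rank matrix with `NA` for missing.
#' @param tau completeness threshold in `[0, 1]`.
#' @return The matrix restricted to the retained columns.
#' @export
missingness_filter <- function(mat, tau) {
  if (tau < 0 || tau > 1) stop("'tau' must be in [0, 1]", call. = FALSE)
  keep <- colMeans(!is.na(mat)) >= tau
  mat[, keep, drop = FALSE]
}

#' Mask cells of the complete submatrix for imputation benchmarking
#'
#' Restricts to the columns with no missing values, masks a uniformly random
#' subset of their cells, and returns the masked matrix together with the
#' ground truth for exactly the masked cells. Imputed values at those cells
#' can then be compared directly to truth (see [nrmse()]).
#'
#' @param mat sample-by-interaction matrix.
#' @param proportion fraction of complete-submatrix cells to mask, in (0, 1);
#'   the masked count is `round(proportion * cells)`.
#' @param seed integer seed; the mask is deterministic given the seed.
#' @return List with `masked` (the input matrix with masked cells set to
#'   `NA`; only complete columns are touched), `cells` (two-column index
#'   matrix of masked positions in `masked`), and `truth` (the original
#'   values at those positions).
#' @export
mask_complete_subset <- function(mat, proportion, seed = 123L) {
  if (proportion <= 0 || proportion >= 1)
    stop("'proportion' must be in (0, 1)", call. = FALSE)
  complete <- which(colSums(is.na(mat)) == 0L)
  if (length(complete) == 0L)
    stop("no complete columns to mask; lower the completeness threshold",
         call. = FALSE)
  n_cells <- nrow(mat) * length(complete)
  n_mask <- round(proportion * n_cells)
  if (n_mask == 0L)
    stop("masking proportion rounds to zero cells; nothing to evaluate",
         call. = FALSE)
  set.seed(as.integer(seed))
  flat <- sample.int(n_cells, n_mask)
  rows <- ((flat - 1L) %% nrow(mat)) + 1L
  cols <- complete[((flat - 1L) %/% nrow(mat)) + 1L]
  cells <- cbind(row = rows, col = cols)
  truth <- mat[cells]
  masked <- mat
  masked[cells] <- NA_real_
  list(masked = masked, cells = cells, truth = truth)
}

#' Impute missing mean ranks
#'
#' Fills every missing cell of the sample-by-interaction matrix. Three
#' imputers are available:
#' \describe{
#'   \item{`random_forest`}{iterative random-forest imputation in the
#'     missForest style, run with interactions as rows (i.e. on the
#'     transposed matrix): missing cells are initialized with column means;
#'     then, visiting columns in order of ascending missingness, each column
#'     with missing values is regressed on all others over its observed rows
#'     and its missing cells are predicted; iterations stop when the sum of
#'     squared changes in the imputed values increases relative to the
#'     previous iteration (the last non-worsening state is returned) or
#'     after `maxiter` iterations. Defaults follow the reference settings:
#'     20 iterations, 500 trees, `mtry = floor(sqrt(p))`, seed 123.}
#'   \item{`knn`}{each missing cell is the inverse-distance-weighted mean of
#'     the `k` nearest sample rows (Euclidean distance over mutually
#'     observed columns, scaled by the number of shared columns) that
#'     observe the column; falls back to the column mean when no neighbour
#'     observes it.}
#'   \item{`mean`}{column mean.}
#' }
#' Observed cells are never altered.
#'
#' @param mat sample-by-interaction matrix with `NA` for missing; every
#'   column must have at least one observed value.
#' @param method one of `"random_forest"`, `"knn"`, `"mean"`.
#' @param ntree,maxiter,mtry random-forest settings; `mtry = NULL` means
#'   `floor(sqrt(p))` over the `p` predictor variables.
#' @param k number of neighbours for `knn`.
#' @param seed integer seed for the random-forest fits.
#' @return The completed matrix.
#' @export
impute_matrix <- function(mat, method = c("random_forest", "knn", "mean"),
                          ntree = 500L, maxiter = 20L, mtry = NULL,
                          k = 10L, seed = 123L) {
  method <- match.arg(method)
  if (any(colSums(!is.na(mat)) == 0L))
    stop("column with zero observed values; filter before imputing",
         call. = FALSE)
  if (!anyNA(mat)) return(mat)
  switch(method,
         mean = .impute_mean(mat),
         knn = .impute_knn(mat, k = k),
         random_forest = .impute_rf(mat, ntree = ntree, maxiter = maxiter,
                                    mtry = mtry, seed = seed))
}

.impute_mean <- function(mat) {
  mu <- colMeans(mat, na.rm = TRUE)
  for (j in seq_len(ncol(mat))) {
    nas <- is.na(mat[, j])
    if (any(nas)) mat[nas, j] <- mu[j]
  }
  mat
}

.impute_knn <- function(mat, k) {
  out <- mat
  mu <- colMeans(mat, na.rm = TRUE)
  obs <- !is.na(mat)
  for (i in which(rowSums(!obs) > 0L)) {
    miss_j <- which(!obs[i, ])
    # mean squared difference over shared columns -> comparable distances
    d <- vapply(seq_len(nrow(mat)), function(r) {
      if (r == i) return(Inf)
      shared <- obs[i, ] & obs[r, ]
      if (!any(shared)) return(Inf)
      sqrt(mean((mat[i, shared] - mat[r, shared])^2))
    }, numeric(1))
    for (j in miss_j) {
      cand <- which(obs[, j] & is.finite(d))
      if (length(cand) == 0L) { out[i, j] <- mu[j]; next }
      cand <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      w <- 1 / (d[cand] + 1e-9)
      out[i, j] <- sum(w * mat[cand, j]) / sum(w)
    }
  }
  out
}

.impute_rf <- function(mat, ntree, maxiter, mtry, seed) {
  set.seed(as.integer(seed))
  # interactions as rows: impute each sample column from the other samples
  w <- t(mat)
  nas <- is.na(w)
  filled <- w
  mu <- colMeans(w, na.rm = TRUE)
  for (j in seq_len(ncol(w))) filled[nas[, j], j] <- mu[j]
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(w) - 1L)))
  col_order <- order(colSums(nas))
  col_order <- col_order[colSums(nas)[col_order] > 0L]
  prev <- filled
  prev_diff <- Inf
  for (it in seq_len(maxiter)) {
    cur <- prev
    for (j in col_order) {
      obs_rows <- !nas[, j]
      # randomForest second-guesses regression on near-discrete responses;
      # rank data legitimately look like that on small fixtures
      fit <- withCallingHandlers(
        randomForest::randomForest(
          x = cur[obs_rows, -j, drop = FALSE], y = w[obs_rows, j],
          ntree = ntree, mtry = min(mtry, ncol(w) - 1L)),
        warning = function(wn) {
          if (grepl("five or fewer unique values", conditionMessage(wn)))
            invokeRestart("muffleWarning")
        })
      cur[nas[, j], j] <- predict(fit, cur[nas[, j], -j, drop = FALSE])
    }
    diff <- sum((cur[nas] - prev[nas])^2)
    if (diff > prev_diff) return(t(prev))   # last non-worsening state
    prev <- cur
    prev_diff <- diff
    if (diff == 0) break
  }
  t(prev)
}

#' Normalized root-mean-squared imputation error on masked cells
#'
#' RMSE of the imputed values over the masked cells, scaled by the
#' population (n-denominator) standard deviation of the true values at those
#' cells. A value of 1 means the prediction error is comparable to the
#' inherent variability of the data (imputing the masked-truth mean gives
#' exactly 1); values below 1 indicate signal beyond a naive mean
#' prediction.
#'
#' @param imputed completed matrix, or a numeric vector of imputed values.
#' @param truth true values at the masked cells.
#' @param cells two-column index matrix of the masked cells (required when
#'   `imputed` is a matrix).
#' @return The NRMSE.
#' @export
nrmse <- function(imputed, truth, cells = NULL) {
  vals <- if (is.matrix(imputed)) {
    if (is.null(cells)) stop("'cells' required with a matrix", call. = FALSE)
    imputed[cells]
  } else imputed
  if (length(vals) != length(truth))
    stop("imputed and truth lengths differ", call. = FALSE)
  if (length(truth) == 0L) stop("empty mask", call. = FALSE)
  pop_sd <- sqrt(mean((truth - mean(truth))^2))
  if (pop_sd == 0) stop("constant truth values: NRMSE undefined",
                        call. = FALSE)
  sqrt(mean((vals - truth)^2)) / pop_sd
}

#' Coarse-plus-fine NRMSE sweep over completeness thresholds
#'
#' Selects the completeness threshold for [missingness_filter()] by masked-
#' entry NRMSE: for each candidate threshold, the matrix is filtered, the
#' filtered matrix's overall missing fraction is measured, the same fraction
#' of cells is masked in its complete column subset, the masked matrix is
#' imputed, and the NRMSE over the masked cells is recorded. A coarse grid
#' from 0 to 1 in steps of 0.1 is evaluated first, then a fine grid in steps
#' of 0.01 within +/- 0.05 of the best coarse threshold (clipped to
#' `[0, 1]`). The threshold with the lowest NRMSE over the union grid wins;
#' ties go to the smaller threshold. Grid points where masking is impossible
#' (no missing values after filtering, no complete columns, or a mask that
#' rounds to zero cells) are recorded as not evaluable and excluded from the
#' argmin.
#'
#' @param mat sample-by-interaction matrix with missing values.
#' @param imputer imputation method passed to [impute_matrix()].
#' @param seed integer seed for masking and the random-forest fits.
#' @param coarse coarse threshold grid (default `seq(0, 1, 0.1)`).
#' @param ... further arguments to [impute_matrix()] (e.g. `ntree`).
#' @return An object of class `imputation_report`: the evaluated grid with
#'   per-threshold NRMSE and missing fraction, the chosen threshold and
#'   imputer, and the mask seed.
#' @export
threshold_sweep <- function(mat, imputer = "random_forest", seed = 123L,
                            coarse = seq(0, 1, by = 0.1), ...) {
  if (length(mat) == 0L) stop("empty matrix", call. = FALSE)
  eval_tau <- function(tau) {
    sub <- missingness_filter(mat, tau)
    if (ncol(sub) == 0L)
      return(c(nrmse = NA_real_, missing_fraction = NA_real_))
    miss_frac <- mean(is.na(sub))
    if (miss_frac == 0 || miss_frac >= 1)
      return(c(nrmse = NA_real_, missing_fraction = miss_frac))
    res <- tryCatch({
      m <- mask_complete_subset(sub, miss_frac, seed = seed)
      imp <- impute_matrix(m$masked, method = imputer, seed = seed, ...)
      nrmse(imp, m$truth, m$cells)
    }, error = function(e) NA_real_)
    c(nrmse = res, missing_fraction = miss_frac)
  }
  coarse <- sort(unique(round(coarse, 10)))
  tab <- t(vapply(coarse, eval_tau, numeric(2)))
  grid <- data.frame(threshold = coarse, tab)
  if (all(is.na(grid$nrmse)))
    stop("no evaluable threshold: matrix has nothing to tune", call. = FALSE)
  best_coarse <- grid$threshold[which.min(grid$nrmse)]
  fine <- setdiff(round(seq(max(0, best_coarse - 0.05),
                            min(1, best_coarse + 0.05), by = 0.01), 10),
                  grid$threshold)
  if (length(fine)) {
    tab2 <- t(vapply(fine, eval_tau, numeric(2)))
    grid <- rbind(grid, data.frame(threshold = fine, tab2))
  }
  grid <- grid[order(grid$threshold), ]
  rownames(grid) <- NULL
  ok <- !is.na(grid$nrmse)
  chosen <- min(grid$threshold[ok][grid$nrmse[ok] == min(grid$nrmse[ok])])
  out <- list(grid = grid, chosen_threshold = chosen,
              chosen_imputer = imputer,
              best_coarse = best_coarse, mask_seed = as.integer(seed),
              masked_fraction =
                grid$missing_fraction[grid$threshold == chosen])
  class(out) <- "imputation_report"
  out
}

#' @export
print.imputation_report <- function(x, ...) {
  cat("NRMSE threshold sweep (", x$chosen_imputer, " imputer)\n", sep = "")
  cat(sprintf("  %d thresholds evaluated; best coarse %.2f\n",
              sum(!is.na(x$grid$nrmse)), x$best_coarse))
  cat(sprintf("  chosen threshold %.2f (NRMSE %.4f, missing fraction %.3f)\n",
              x$chosen_threshold,
              min(x$grid$nrmse, na.rm = TRUE), x$masked_fraction))
  invisible(x)
}
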