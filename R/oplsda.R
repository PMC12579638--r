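#' Orthogonalized partial least squares discriminant analysis
#'
#' Fits an OPLS-DA model for a two-class problem: features are centered and
#' scaled to unit variance, the class labels are encoded +/-1 and centered,
#' `n_orthogonal` components capturing variation orthogonal to the class
#' contrast are extracted and removed from the feature matrix (orthogonal
#' signal correction), and a single predictive PLS component is fitted on
#' the deflated matrix. Because the orthogonal weight vectors are
#' constructed orthogonal to the y-correlated weight vector, the orthogonal
#' scores have exactly zero correlation with the class labels, and the
#' predictive and orthogonal score vectors are mutually orthogonal.
#'
#' A new sample is classified by projecting it (after scaling and removal of
#' the orthogonal components) onto the predictive component and assigning
#' the class whose training score mean is nearer.
#'
#' @param X numeric feature matrix (samples x features); no constant
#'   feature.
#' @param y binary labels (factor, character or numeric with two distinct
#'   values).
#' @param n_orthogonal number of orthogonal components (default 1; reduced
#'   automatically when the data admit fewer, e.g. a single feature admits
#'   none).
#' @return An object of class `oplsda` with centering/scaling vectors, class
#'   encoding, predictive weights/loadings/scores, per-component orthogonal
#'   weights/loadings/scores, VIP scores (see [vip()]), and training fit.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40 * 5), 40, 5)
#' y <- rep(c("A", "B"), each = 20)
#' X[y == "B", 1] <- X[y == "B", 1] + 4
#' m <- fit_oplsda(X, y)
#' table(predict(m, X), y)
#' @export
fit_oplsda <- function(X, y, n_orthogonal = 1L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly two classes", call. = FALSE)
  if (nrow(X) != length(y)) stop("X and y sizes differ", call. = FALSE)
  if (nrow(X) <= n_orthogonal + 1L)
    stop("need more samples than n_orthogonal + 1", call. = FALSE)
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    nm <- colnames(X)[which(sds == 0)[1]]
    stop("constant feature: ", if (is.null(nm)) which(sds == 0)[1] else nm,
         call. = FALSE)
  }
  core <- .oplsda_core(X, y, n_orthogonal)
  core$call <- match.call()
  class(core) <- "oplsda"
  core
}

# lean fitting routine shared by fit_oplsda and the cross-validation loop;
# assumes validated two-class input
.oplsda_core <- function(X, y, n_orthogonal) {
  lev <- levels(y)
  yn <- ifelse(y == lev[2], 1, -1)
  mu <- colMeans(X)
  sds <- apply(X, 2L, sd)
  sds[sds == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sds, "/")
  yc <- yn - mean(yn)
  p <- ncol(Xs)

  w <- drop(crossprod(Xs, yc))
  w <- w / sqrt(sum(w^2))
  n_orth <- min(n_orthogonal, p - 1L)
  W_o <- P_o <- matrix(0, p, 0)
  T_o <- matrix(0, nrow(Xs), 0)
  j <- 0L
  while (j < n_orth) {
    t <- drop(Xs %*% w)
    pl <- drop(crossprod(Xs, t)) / sum(t^2)
    w_o <- pl - sum(w * pl) * w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-10) break            # no orthogonal variation left
    w_o <- w_o / nrm
    t_o <- drop(Xs %*% w_o)
    p_o <- drop(crossprod(Xs, t_o)) / sum(t_o^2)
    Xs <- Xs - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
    j <- j + 1L
  }
  t <- drop(Xs %*% w)
  pl <- drop(crossprod(Xs, t)) / sum(t^2)
  q <- sum(yc * t) / sum(t^2)
  class_means <- c(mean(t[yn == -1]), mean(t[yn == 1]))
  vip <- sqrt(p) * abs(w)            # single predictive component
  names(vip) <- colnames(X)
  list(center = mu, scale = sds,
       class_encoding = stats::setNames(c(-1, 1), lev), levels = lev,
       n_orthogonal = ncol(W_o),
       predictive_weights = stats::setNames(w, colnames(X)),
       predictive_loadings = stats::setNames(pl, colnames(X)),
       predictive_scores = t, q = q,
       orthogonal_weights = W_o, orthogonal_loadings = P_o,
       orthogonal_scores = T_o,
       class_score_means = stats::setNames(class_means, lev),
       vip = vip, y = y)
}

.oplsda_scores <- function(object, newdata) {
  Xn <- as.matrix(newdata)
  Xn <- sweep(sweep(Xn, 2L, object$center), 2L, object$scale, "/")
  if (object$n_orthogonal > 0L) {
    for (j in seq_len(object$n_orthogonal)) {
      t_o <- drop(Xn %*% object$orthogonal_weights[, j])
      Xn <- Xn - tcrossprod(t_o, object$orthogonal_loadings[, j])
    }
  }
  drop(Xn %*% object$predictive_weights)
}

#' Predict method for OPLS-DA models
#'
#' @param object a fitted [fit_oplsda()] model.
#' @param newdata matrix with the same features as the training data;
#'   defaults to the training scores/classes.
#' @param type `"class"` (default) for predicted labels, `"scores"` for
#'   predictive-component scores.
#' @param ... unused.
#' @export
predict.oplsda <- function(object, newdata = NULL,
                           type = c("class", "scores"), ...) {
  type <- match.arg(type)
  t_new <- if (is.null(newdata)) object$predictive_scores
    else .oplsda_scores(object, newdata)
  if (type == "scores") return(t_new)
  m <- object$class_score_means
  lab <- ifelse(abs(t_new - m[1]) <= abs(t_new - m[2]),
                object$levels[1], object$levels[2])
  factor(lab, levels = object$levels)
}

#' Variable importance in projection
#'
#' The standard VIP score over the predictive component(s):
#' `vip_j = sqrt(p * sum_a w_ja^2 SSY_a / sum_a SSY_a)` with normalized
#' weights `w`. With a single predictive component this reduces to
#' `sqrt(p) * |w_j|`. By construction the mean of the squared VIP scores is
#' 1, so VIP > 1 marks features with above-average contribution to the
#' class separation.
#'
#' @param model a fitted [fit_oplsda()] model.
#' @return Named numeric vector of VIP scores.
#' @export
vip <- function(model) {
  if (!inherits(model, "oplsda") || is.null(model$vip))
    stop("'model' must be a fitted oplsda model", call. = FALSE)
  model$vip
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA model: %d features, %d samples, %d orthogonal component(s)\n",
    length(x$predictive_weights), length(x$predictive_scores),
    x$n_orthogonal))
  cat("  classes: ", paste(x$levels, collapse = " vs "), "\n", sep = "")
  acc <- mean(predict(x) == x$y)
  cat(sprintf("  training accuracy %.3f; %d feature(s) with VIP > 1\n",
              acc, sum(x$vip > 1)))
  if (!is.null(x$cv_accuracy))
    cat(sprintf("  cross-validated accuracy %.3f\n", x$cv_accuracy))
  if (!is.null(x$permutation))
    cat(sprintf("  permutation p-value %.4g (%d permutations)\n",
                x$permutation$p_value, x$permutation$n_permutations))
  invisible(x)
}

#' @export
summary.oplsda <- function(object, ...) {
  print(object)
  cat("\nTop features by VIP:\n")
  top <- sort(object$vip, decreasing = TRUE)
  print(round(head(top, 10L), 3))
  invisible(object)
}

#' @export
coef.oplsda <- function(object, ...) {
  cbind(weight = object$predictive_weights,
        loading = object$predictive_loadings, vip = object$vip)
}

#' @export
fitted.oplsda <- function(object, ...) object$predictive_scores * object$q

#' @export
residuals.oplsda <- function(object, ...) {
  yn <- ifelse(object$y == object$levels[2], 1, -1)
  (yn - mean(yn)) - fitted(object)
}

#' Score plot for an OPLS-DA model
#'
#' Plots the predictive-component scores against the first orthogonal
#' component (or sample index when no orthogonal component was extracted),
#' colored by class.
#'
#' @param x a fitted [fit_oplsda()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.oplsda <- function(x, ...) {
  t1 <- x$predictive_scores
  if (x$n_orthogonal > 0L) {
    t2 <- x$orthogonal_scores[, 1]
    ylab <- "orthogonal component 1"
  } else {
    t2 <- seq_along(t1)
    ylab <- "sample index"
  }
  cols <- c("#E69F00", "#0072B2")[as.integer(x$y)]
  plot(t1, t2, col = cols, pch = 19,
       xlab = "predictive component", ylab = ylab, ...)
  abline(v = mean(x$class_score_means), lty = 2, col = "grey50")
  legend("topright", legend = x$levels, col = c("#E69F00", "#0072B2"),
         pch = 19, bty = "n")
  invisible(x)
}

#' Stratified k-fold cross-validated accuracy of an OPLS-DA classifier
#'
#' Splits the samples into `k` stratified folds, fits the model on each
#' training set, predicts the held-out fold, and returns the overall
#' fraction of correct predictions.
#'
#' @param X,y as in [fit_oplsda()]; each class needs at least `k` samples.
#' @param k number of folds (default 5).
#' @param n_orthogonal orthogonal components per fold model.
#' @param seed integer seed controlling the fold shuffle.
#' @return The cross-validated accuracy.
#' @export
cross_validate <- function(X, y, k = 5L, n_orthogonal = 1L, seed = 1L) {
  set.seed(as.integer(seed))
  .cv_accuracy(as.matrix(X), as.factor(y), k, n_orthogonal)
}

# CV loop drawing fold assignments from the current RNG stream
.cv_accuracy <- function(X, y, k, n_orthogonal) {
  if (nlevels(droplevels(y)) != 2L)
    stop("y must have exactly two classes", call. = FALSE)
  if (any(table(y) < k))
    stop("a class has fewer samples than folds; use a smaller k",
         call. = FALSE)
  foldid <- .stratified_folds(y, k)
  correct <- 0L
  for (f in seq_len(k)) {
    test <- foldid == f
    m <- .oplsda_core(X[!test, , drop = FALSE], droplevels(y[!test]),
                      n_orthogonal)
    t_new <- .oplsda_scores(m, X[test, , drop = FALSE])
    mm <- m$class_score_means
    lab <- ifelse(abs(t_new - mm[1]) <= abs(t_new - mm[2]),
                  m$levels[1], m$levels[2])
    correct <- correct + sum(lab == as.character(y[test]))
  }
  correct / length(y)
}

#' Empirical p-value convention for permutation tests
#'
#' The empirical p-value is the fraction of null models performing at least
#' as well as the observed model, floored at `1/n`:
#' `p = max(k_at_least, 1) / n_permutations`. A model beating 989 of 1000
#' nulls (11 at least as good) thus has p = 0.011, and a model beating all
#' 1000 has p = 0.001.
#'
#' @param k_at_least number of null models performing at least as well as
#'   the observed model.
#' @param n_permutations number of permutations (>= 1).
#' @return The empirical p-value in (0, 1].
#' @export
empirical_p <- function(k_at_least, n_permutations) {
  if (n_permutations < 1) stop("'n_permutations' must be >= 1", call. = FALSE)
  if (k_at_least < 0 || k_at_least > n_permutations)
    stop("'k_at_least' must be in [0, n_permutations]", call. = FALSE)
  max(k_at_least, 1) / n_permutations
}

#' Construct a permutation record from observed and null metrics
#'
#' Counts the null metrics at least as large as the observed metric (ties
#' count against the model) and applies the [empirical_p()] convention.
#'
#' @param observed_metric observed model performance (e.g. CV accuracy).
#' @param null_metrics numeric vector of null-model performances.
#' @return An object of class `permutation_record` with `n_permutations`,
#'   `observed_metric`, `null_metrics`, `k_at_least`, `p_value`.
#' @export
permutation_record <- function(observed_metric, null_metrics) {
  n <- length(null_metrics)
  k <- sum(null_metrics >= observed_metric)
  out <- list(n_permutations = n, observed_metric = observed_metric,
              null_metrics = null_metrics, k_at_least = k,
              p_value = empirical_p(k, n))
  class(out) <- "permutation_record"
  out
}

#' @export
print.permutation_record <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed %.3f vs %d null models (mean %.3f)\n",
    x$observed_metric, x$n_permutations, mean(x$null_metrics)))
  cat(sprintf("  %d null(s) at least as good; empirical p = %.4g\n",
              x$k_at_least, x$p_value))
  invisible(x)
}

#' Label-permutation test of cross-validated accuracy
#'
#' Compares the cross-validated accuracy of the OPLS-DA classifier on the
#' true labels against `n_permutations` models fitted to label-shuffled
#' copies of the data, and reports the empirical p-value (fraction of null
#' models at least as accurate, floored at `1/n`).
#'
#' @param X,y,k,n_orthogonal as in [cross_validate()].
#' @param n_permutations number of label permutations (default 1000).
#' @param seed integer seed for both the fold shuffles and the label
#'   permutations.
#' @return A [permutation_record()].
#' @export
permutation_test <- function(X, y, k = 5L, n_permutations = 1000L,
                             n_orthogonal = 1L, seed = 1L) {
  if (n_permutations < 1) stop("'n_permutations' must be >= 1", call. = FALSE)
  X <- as.matrix(X)
  y <- as.factor(y)
  set.seed(as.integer(seed))
  observed <- .cv_accuracy(X, y, k, n_orthogonal)
  nulls <- vapply(seq_len(n_permutations), function(i) {
    .cv_accuracy(X, sample(y), k, n_orthogonal)
  }, numeric(1))
  permutation_record(observed, nulls)
}

#' Two-stage OPLS-DA fit with VIP-based feature reduction
#'
#' Fits a first OPLS-DA model on all (stability-retained) features, keeps
#' the features with VIP > 1 (above-average contribution), and fits a
#' second model on that reduced set. The second-stage model carries the
#' cross-validated accuracy and the permutation record.
#'
#' @param X,y,k,n_orthogonal,n_permutations,seed as in
#'   [permutation_test()]; `k` is also the CV fold count.
#' @param vip_cutoff VIP threshold for the second stage (default 1).
#' @return List with `stage1`, `stage2` (both `oplsda` objects; `stage2`
#'   has `cv_accuracy` and `permutation` filled in) and `features` (the
#'   second-stage feature ids).
#' @export
two_stage_fit <- function(X, y, k = 5L, n_permutations = 1000L,
                          n_orthogonal = 1L, vip_cutoff = 1,
                          seed = 1L) {
  X <- as.matrix(X)
  stage1 <- fit_oplsda(X, y, n_orthogonal = n_orthogonal)
  keep <- names(which(vip(stage1) > vip_cutoff))
  if (length(keep) == 0L)
    stop("no feature with VIP > ", vip_cutoff,
         "; stage-1 VIP range [", sprintf("%.3f", min(stage1$vip)), ", ",
         sprintf("%.3f", max(stage1$vip)), "]", call. = FALSE)
  stage2 <- fit_oplsda(X[, keep, drop = FALSE], y,
                       n_orthogonal = n_orthogonal)
  stage2$cv_accuracy <- cross_validate(X[, keep, drop = FALSE], y, k = k,
                                       n_orthogonal = n_orthogonal,
                                       seed = seed)
  stage2$permutation <- permutation_test(X[, keep, drop = FALSE], y, k = k,
                                         n_permutations = n_permutations,
                                         n_orthogonal = n_orthogonal,
                                         seed = seed + 1L)
  list(stage1 = stage1, stage2 = stage2, features = keep)
}
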