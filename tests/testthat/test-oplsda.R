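test_that("well-separated classes are fitted perfectly", {
  d <- gaussian_classes(n = 40, d = 10, sep = 5, seed = 1)
  m <- fit_oplsda(d$X, d$y)
  expect_s3_class(m, "oplsda")
  expect_equal(mean(predict(m, d$X) == d$y), 1.0)
  sc <- predict(m, d$X, type = "scores")
  expect_true(all(sign(sc[d$y == "A"]) != sign(sc[d$y == "B"])))
})

test_that("label swap negates scores and preserves VIP", {
  d <- gaussian_classes(seed = 2)
  m1 <- fit_oplsda(d$X, d$y)
  m2 <- fit_oplsda(d$X, ifelse(d$y == "A", "B", "A"))
  expect_equal(m2$predictive_scores, -m1$predictive_scores)
  expect_equal(vip(m2), vip(m1))
})

test_that("single-feature model is a univariate threshold with VIP 1", {
  set.seed(3)
  # gap around zero: the fitted threshold (class-score midpoint) then
  # reproduces the generating rule exactly
  x <- matrix(sample(c(runif(15, -2, -0.5), runif(15, 0.5, 2))), 30, 1,
              dimnames = list(NULL, "f"))
  y <- ifelse(x[, 1] > 0, "hi", "lo")
  m <- fit_oplsda(x, y, n_orthogonal = 0)
  expect_identical(unname(vip(m)), 1)
  expect_equal(as.character(predict(m, x)), y)
})

test_that("VIP normalization holds for every fitted model", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30; p <- sample(2:15, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c("A", "B"), length.out = n)
    m <- fit_oplsda(X, y, n_orthogonal = sample(0:2, 1))
    expect_equal(mean(vip(m)^2), 1, tolerance = 1e-8)
  }
  # identical columns share the weight equally: all VIP exactly 1
  set.seed(6)
  x0 <- rnorm(20)
  Xd <- cbind(a = x0, b = x0, c = x0)
  yd <- rep(c("A", "B"), each = 10)
  expect_equal(unname(vip(fit_oplsda(Xd, yd, n_orthogonal = 0))),
               rep(1, 3), tolerance = 1e-12)
})

test_that("a planted discriminative feature gets the top VIP > 1", {
  d <- gaussian_classes(n = 40, d = 10, sep = 4, seed = 7)
  v <- vip(fit_oplsda(d$X, d$y))
  expect_equal(names(which.max(v)), "f1")
  expect_gt(v["f1"], 1)
})

test_that("orthogonal components are orthogonal to y and to the scores", {
  d <- gaussian_classes(n = 40, d = 8, sep = 3, seed = 8)
  m <- fit_oplsda(d$X, d$y, n_orthogonal = 2)
  yn <- ifelse(d$y == "B", 1, -1)
  yc <- yn - mean(yn)
  for (j in seq_len(m$n_orthogonal)) {
    expect_lt(abs(sum(m$orthogonal_scores[, j] * yc)), 1e-8)
    expect_lt(abs(sum(m$orthogonal_scores[, j] * m$predictive_scores)), 1e-8)
  }
})

test_that("predictions and VIP are invariant to feature rescaling", {
  d <- gaussian_classes(seed = 9)
  m1 <- fit_oplsda(d$X, d$y)
  X2 <- d$X
  X2[, 3] <- X2[, 3] * 7
  m2 <- fit_oplsda(X2, d$y)
  expect_equal(vip(m2), vip(m1), tolerance = 1e-10)
  expect_equal(predict(m2, X2), predict(m1, d$X))
  Xc <- d$X; Xc[, 2] <- 1
  expect_error(fit_oplsda(Xc, d$y), "constant feature")
})

test_that("cross-validation is accurate, calibrated and deterministic", {
  d <- gaussian_classes(n = 40, d = 10, sep = 5, seed = 10)
  expect_gte(cross_validate(d$X, d$y, seed = 1), 0.95)
  set.seed(11)
  null_y <- sample(rep(c("A", "B"), each = 20))
  Xn <- matrix(rnorm(40 * 10), 40, 10)
  acc <- cross_validate(Xn, null_y, seed = 2)
  expect_gte(acc, 0.3)
  expect_lte(acc, 0.7)
  expect_identical(cross_validate(d$X, d$y, seed = 3),
                   cross_validate(d$X, d$y, seed = 3))
  both <- c(1:4, 21:24)               # four samples per class, fewer than k
  expect_error(cross_validate(d$X[both, ], d$y[both], k = 5), "smaller k")
})

test_that("the empirical p-value convention is exact", {
  expect_equal(empirical_p(11, 1000), 0.011)
  expect_equal(empirical_p(0, 1000), 0.001)       # floored at 1/N
  expect_equal(empirical_p(1000, 1000), 1.0)
  expect_error(empirical_p(-1, 100), "k_at_least")
  expect_error(empirical_p(0, 0), "n_permutations")

  rec <- permutation_record(0.9, c(rep(0.5, 97), 0.9, 0.95, 1.0))
  expect_equal(rec$k_at_least, 3L)                 # ties count against
  expect_equal(rec$p_value, 0.03)
  expect_length(rec$null_metrics, rec$n_permutations)
})

test_that("permutation test separates signal from its shuffled nulls", {
  d <- gaussian_classes(n = 30, d = 5, sep = 5, seed = 12)
  rec <- permutation_test(d$X, d$y, n_permutations = 50, seed = 4)
  expect_s3_class(rec, "permutation_record")
  expect_equal(rec$p_value,
               max(rec$k_at_least, 1) / rec$n_permutations)
  expect_lte(rec$p_value, 0.05)
  expect_gte(rec$observed_metric, 0.95)
  expect_gt(rec$observed_metric, max(rec$null_metrics) - 0.2)
})

test_that("two-stage fit reduces to the above-average VIP features", {
  set.seed(13)
  n <- 40
  y <- rep(c("A", "B"), each = n / 2)
  planted <- matrix(rnorm(n * 3), n, 3) + ifelse(y == "B", 3, 0)
  X <- cbind(planted, matrix(rnorm(n * 7), n, 7))
  colnames(X) <- c(paste0("p", 1:3), paste0("n", 1:7))
  fit <- two_stage_fit(X, y, n_permutations = 20, seed = 5)
  expect_true(all(fit$features %in% colnames(X)))
  expect_true(all(paste0("p", 1:3) %in% fit$features))
  expect_true(all(vip(fit$stage1)[fit$features] > 1))
  expect_false(is.null(fit$stage2$cv_accuracy))
  expect_s3_class(fit$stage2$permutation, "permutation_record")

  # all-identical features: every VIP exactly 1, no feature above average
  x0 <- rnorm(n)
  Xsame <- cbind(a = x0, b = x0, c = x0)
  expect_error(two_stage_fit(Xsame, y, n_permutations = 5, seed = 1),
               "no feature with VIP")
})

test_that("stage-2 accuracy does not collapse for a single strong feature", {
  set.seed(14)
  n <- 40
  y <- rep(c("A", "B"), each = n / 2)
  X <- cbind(s = rnorm(n) + ifelse(y == "B", 5, 0),
             matrix(rnorm(n * 9), n, 9))
  colnames(X) <- c("s", paste0("n", 1:9))
  fit <- two_stage_fit(X, y, n_permutations = 20, seed = 6)
  acc1 <- cross_validate(X, y, seed = 6)
  expect_true("s" %in% fit$features)
  expect_gte(fit$stage2$cv_accuracy, acc1 - 0.1)
})
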