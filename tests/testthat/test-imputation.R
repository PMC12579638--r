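test_that("completeness filter keeps the inclusive boundary", {
  mat <- matrix(1, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  mat[1:3, 1] <- NA       # 7/10 present
  mat[1:4, 2] <- NA       # 6/10 present
  expect_equal(colnames(missingness_filter(mat, 0.7)), c("a", "c"))
  expect_identical(missingness_filter(mat, 0), mat)
  expect_equal(colnames(missingness_filter(mat, 1)), "c")
  expect_error(missingness_filter(mat, 1.2), "tau")
})

test_that("masking selects the right number of cells, reproducibly", {
  set.seed(1)
  mat <- matrix(rnorm(100), 10, 10)
  m <- mask_complete_subset(mat, 0.2, seed = 5)
  expect_equal(nrow(m$cells), 20L)
  expect_equal(sum(is.na(m$masked)), 20L)
  expect_equal(m$truth, mat[m$cells])
  expect_identical(m, mask_complete_subset(mat, 0.2, seed = 5))
  expect_error(mask_complete_subset(mat, 0.001), "zero cells")
  mat2 <- mat; mat2[1, ] <- NA      # no complete column
  expect_error(mask_complete_subset(mat2, 0.2), "no complete columns")
})

test_that("imputers fill only missing cells and are exact on identities", {
  set.seed(2)
  mat <- matrix(rnorm(60, 10), 10, 6)
  for (meth in c("random_forest", "knn", "mean"))
    expect_identical(impute_matrix(mat, meth, ntree = 20), mat)

  m2 <- mat
  m2[c(1, 4), 3] <- NA
  m2[2, 5] <- NA
  for (meth in c("random_forest", "knn", "mean")) {
    imp <- impute_matrix(m2, meth, ntree = 20, maxiter = 3)
    expect_false(anyNA(imp))
    obs <- !is.na(m2)
    expect_identical(imp[obs], m2[obs])   # observed cells untouched
  }
  m3 <- matrix(c(2, 4, NA, 1, 1, 1), 3, 2)
  expect_equal(impute_matrix(m3, "mean")[3, 1], 3)
  m4 <- mat; m4[, 2] <- NA
  expect_error(impute_matrix(m4, "mean"), "zero observed")
})

test_that("random-forest imputation is deterministic under its seed", {
  set.seed(3)
  mat <- matrix(rnorm(80, 5), 10, 8)
  mat[sample(80, 12)] <- NA
  a <- impute_matrix(mat, "random_forest", ntree = 30, maxiter = 3, seed = 9)
  b <- impute_matrix(mat, "random_forest", ntree = 30, maxiter = 3, seed = 9)
  expect_identical(a, b)
})

test_that("model-based imputers beat the mean on collinear columns", {
  set.seed(4)
  u <- runif(12, 1, 10)
  a <- runif(15, 0.5, 3); b <- runif(15, 0, 5)
  base <- sapply(seq_along(a), function(j) a[j] * u + b[j])
  mat <- cbind(base, base)            # exactly collinear pairs
  colnames(mat) <- paste0("c", seq_len(ncol(mat)))
  m <- mask_complete_subset(mat, 0.1, seed = 6)
  err <- vapply(c(random_forest = "random_forest", knn = "knn",
                  mean = "mean"), function(meth) {
    nrmse(impute_matrix(m$masked, meth, ntree = 100, maxiter = 5),
          m$truth, m$cells)
  }, numeric(1))
  expect_lt(err["random_forest"], err["mean"])
  expect_lt(err["knn"], err["mean"])
})

test_that("NRMSE identities hold", {
  truth <- c(0, 2)
  expect_equal(nrmse(c(0, 2), truth), 0)            # perfect imputation
  expect_equal(nrmse(c(1, 1), truth), 1)            # RMSE 1 / sd 1
  set.seed(5)
  t2 <- rnorm(200, 3, 2)
  expect_equal(nrmse(rep(mean(t2), 200), t2), 1)    # mean imputer identity
  expect_error(nrmse(c(1, 1), c(3, 3)), "constant truth")
  expect_error(nrmse(numeric(0), numeric(0)), "empty mask")
})

test_that("threshold sweep evaluates a coarse-plus-fine grid and tunes", {
  # clean block: strongly collinear and complete; junk block: noisy with
  # heavy dropout -- higher thresholds discard the junk and imputation of
  # the remaining collinear columns improves
  set.seed(6)
  n <- 20
  u <- runif(n, 1, 10)
  clean <- cbind(u, 2 * u, 3 * u, 4 * u, 5 * u) +
    matrix(rnorm(n * 5, sd = 0.05), n)
  junk <- matrix(runif(n * 10, 1, 10), n)
  junk[sample(length(junk), round(0.4 * length(junk)))] <- NA
  mat <- cbind(clean, junk)
  colnames(mat) <- paste0("c", seq_len(ncol(mat)))
  rep <- threshold_sweep(mat, imputer = "knn", seed = 7)
  expect_s3_class(rep, "imputation_report")
  fine <- round(seq(max(0, rep$best_coarse - 0.05),
                    min(1, rep$best_coarse + 0.05), by = 0.01), 10)
  expect_true(all(fine %in% rep$grid$threshold))
  ok <- !is.na(rep$grid$nrmse)
  expect_equal(rep$chosen_threshold,
               min(rep$grid$threshold[ok][rep$grid$nrmse[ok] ==
                                            min(rep$grid$nrmse[ok])]))
  expect_gte(rep$chosen_threshold, stats::median(rep$grid$threshold[ok]))

  complete <- matrix(rnorm(40), 10, 4)
  expect_error(threshold_sweep(complete, imputer = "mean"),
               "no evaluable threshold")
})
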