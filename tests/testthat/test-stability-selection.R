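test_that("log10 transform is exact and guards its domain", {
  expect_equal(log10_transform(matrix(c(1, 1000, 4701), 1)),
               matrix(c(0, 3, log10(4701)), 1))
  expect_error(log10_transform(matrix(c(1, -2), 1)), "> 0")
  expect_error(log10_transform(matrix(c(1, NA), 1)), "complete")
})

test_that("a strongly separating feature is always selected", {
  set.seed(10)
  n <- 20
  y <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * 300), n, 300)
  X[y == "B", 1] <- X[y == "B", 1] + 8      # complete separation, big margin
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  sel <- stability_lasso(X, y, n_repeats = 50, seed = 1)
  expect_equal(unname(sel$frequency["f1"]), 1.0)
  expect_true("f1" %in% sel$retained)
})

test_that("permuted labels retain nothing", {
  set.seed(11)
  n <- 30
  X <- matrix(rnorm(n * 50), n, 50)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- sample(rep(c("A", "B"), each = n / 2))
  sel <- stability_lasso(X, y, n_repeats = 50, seed = 2)
  expect_length(sel$retained, 0L)
})

test_that("duplicated columns are handled and share the selections", {
  set.seed(12)
  n <- 20
  y <- rep(c("A", "B"), each = n / 2)
  x1 <- rnorm(n) + ifelse(y == "B", 6, 0)
  noise <- matrix(rnorm(n * 20), n, 20)
  single <- cbind(f = x1, noise)
  colnames(single) <- c("f", paste0("n", 1:20))
  dup <- cbind(f = x1, fdup = x1, noise)
  colnames(dup) <- c("f", "fdup", paste0("n", 1:20))
  s1 <- stability_lasso(single, y, n_repeats = 40, seed = 3)
  s2 <- stability_lasso(dup, y, n_repeats = 40, seed = 3)
  expect_gte(s2$frequency["f"] + s2$frequency["fdup"],
             s1$frequency["f"] - 0.1)
})

test_that("selection frequencies are reproducible under a fixed seed", {
  set.seed(13)
  X <- matrix(rnorm(20 * 30), 20, 30)
  colnames(X) <- paste0("f", 1:30)
  y <- rep(c("A", "B"), each = 10)
  a <- stability_lasso(X, y, n_repeats = 20, seed = 7)
  b <- stability_lasso(X, y, n_repeats = 20, seed = 7)
  expect_identical(a$frequency, b$frequency)
  expect_error(stability_lasso(X, rep("A", 20), n_repeats = 5), "two classes")
})

test_that("stronger planted shifts never lower planted selection", {
  # a single planted feature isolates the shift effect from the
  # redundancy-driven competition that arises among several planted features
  freq_for <- function(shift, seed) {
    cfg <- simulation_config(n_samples_per_group = 10, n_cell_types = 3,
                             n_lr_pairs = 100, n_discriminative = 1,
                             rank_shift = shift, method_noise_sd = 40,
                             missing_rate = 0, seed = seed)
    sim <- simulate_interaction_cohort(cfg)
    mat <- build_rank_matrix(sim$tables, sim$metadata)
    sel <- stability_lasso(log10_transform(mat), sim$metadata$response,
                           n_repeats = 30, seed = seed)
    mean(sel$frequency[sim$truth$discriminative_keys])
  }
  for (seed in c(1, 2)) {
    f <- vapply(c(0, 60, 150), freq_for, numeric(1), seed = seed)
    expect_lte(f[1], f[2] + 0.05)
    expect_lte(f[2], f[3] + 0.05)
    expect_gt(f[3], 0.9)
  }
})

test_that("pruning loop removes excluded features and terminates", {
  set.seed(14)
  n <- 20
  y <- rep(c("A", "B"), each = n / 2)
  shift <- ifelse(y == "B", 6, 0)
  X <- cbind(p1 = rnorm(n) + shift, p2 = rnorm(n) + shift,
             matrix(rnorm(n * 15), n, 15))
  colnames(X) <- c("p1", "p2", paste0("n", 1:15))

  plain <- stability_lasso(X, y, n_repeats = 30, seed = 4)
  noex <- prune_and_rerun(X, y, exclusion = character(0),
                          n_repeats = 30, seed = 4)
  expect_identical(noex$selection$frequency, plain$frequency)
  expect_length(noex$pruning, 0L)

  pruned <- prune_and_rerun(X, y, exclusion = "p1",
                            reasons = "intracellular localization",
                            n_repeats = 30, seed = 4)
  expect_false("p1" %in% pruned$selection$feature_ids)
  expect_true("p2" %in% pruned$selection$retained)
  expect_gte(length(pruned$pruning), 1L)
  expect_equal(pruned$pruning[[1]]$excluded_features, "p1")
  expect_equal(pruned$pruning[[1]]$reasons, "intracellular localization")
  expect_warning(prune_and_rerun(X, y, exclusion = "absent",
                                 n_repeats = 5, seed = 1), "not present")
})
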