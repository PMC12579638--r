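test_that("configuration invariants are enforced", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_samples_per_group = 0), "count")
  expect_error(simulation_config(n_discriminative = 10, n_lr_pairs = 5),
               "n_lr_pairs")
  expect_error(simulation_config(missing_rate = 1), "missing_rate")
  expect_error(simulation_config(missing_rate = 0.6,
                                 group_missing_delta = 0.5), "< 1")
})

test_that("identical seeds give byte-identical cohorts", {
  cfg <- simulation_config(n_samples_per_group = 4, n_lr_pairs = 60,
                           seed = 11)
  expect_identical(simulate_interaction_cohort(cfg),
                   simulate_interaction_cohort(cfg))
})

test_that("no dropout keeps every interaction in every sample", {
  cfg <- simulation_config(n_samples_per_group = 3, n_lr_pairs = 50,
                           missing_rate = 0, seed = 2)
  sim <- simulate_interaction_cohort(cfg)
  expect_true(all(vapply(sim$tables, nrow, integer(1)) == 50L))
})

test_that("null configuration produces exchangeable groups", {
  cfg <- simulation_config(n_samples_per_group = 10, n_lr_pairs = 200,
                           n_discriminative = 0, rank_shift = 0,
                           method_noise_sd = 40, missing_rate = 0, seed = 5)
  sim <- simulate_interaction_cohort(cfg)
  mat <- build_rank_matrix(sim$tables, sim$metadata)
  y <- sim$metadata$response
  p <- apply(mat, 2L, function(v) wilcoxon_two_group(v, y)$p_value)
  # rejections at the nominal level, within a generous binomial band
  expect_gt(mean(p <= 0.05), 0.005)
  expect_lt(mean(p <= 0.05), 0.12)
})

test_that("rank shift displaces planted features monotonically", {
  diff_for <- function(shift) {
    # resource large enough that shifted planted ranks stay clear of the
    # [1, n] clipping boundaries
    cfg <- simulation_config(n_samples_per_group = 8, n_lr_pairs = 1000,
                             n_discriminative = 8, rank_shift = shift,
                             method_noise_sd = 30, missing_rate = 0,
                             seed = 42)
    sim <- simulate_interaction_cohort(cfg)
    mat <- build_rank_matrix(sim$tables, sim$metadata)
    y <- sim$metadata$response
    planted <- sim$truth$discriminative_keys
    mean(colMeans(mat[y == "NR", planted]) -
           colMeans(mat[y == "R", planted]))
  }
  d <- vapply(c(0, 40, 120), diff_for, numeric(1))
  expect_lt(abs(d[1]), 20)            # no planted effect at zero shift
  expect_gt(d[2], d[1])
  expect_gt(d[3], d[2])
  expect_equal(d[3], 120, tolerance = 0.2)
})

test_that("group-dependent dropout thins the NR group", {
  cfg <- simulation_config(n_samples_per_group = 6, n_lr_pairs = 200,
                           missing_rate = 0.2, group_missing_delta = 0.3,
                           seed = 3)
  sim <- simulate_interaction_cohort(cfg)
  sizes <- vapply(sim$tables, nrow, integer(1))
  grp <- sim$truth$group_of_sample[names(sizes)]
  expect_equal(unname(sizes[grp == "R"]), rep(160L, 6))   # 20% dropout
  expect_equal(unname(sizes[grp == "NR"]), rep(100L, 6))  # 50% dropout
})

test_that("aggregate rank is a monotone proxy in (0, 1]", {
  sim <- small_cohort(seed = 9, missing = 0)
  for (tab in sim$tables[1:3]) {
    expect_true(all(tab$aggregate_rank > 0 & tab$aggregate_rank <= 1))
    # both quantities carry independent noise around the latent rank, so
    # the association is strong but not perfect
    expect_gt(cor(tab$aggregate_rank, tab$mean_rank,
                  method = "spearman"), 0.6)
  }
})

test_that("survival cohort is standardized, deterministic and validated", {
  genes <- paste0("G", 1:8)
  sc <- simulate_survival_cohort(60, genes, hazard_ratio = 2,
                                 censor_rate = 0.2, seed = 4)
  expect_equal(unname(colMeans(sc$z)), rep(0, 8), tolerance = 1e-8)
  expect_equal(unname(apply(sc$z, 2, sd)), rep(1, 8), tolerance = 1e-8)
  expect_true(all(sc$os_months >= 0))
  expect_true(all(sc$event %in% c(0L, 1L)))
  expect_identical(sc, simulate_survival_cohort(60, genes, 2, 0.2, seed = 4))
  expect_error(simulate_survival_cohort(60, character(0), 2), "non-empty")
  expect_error(simulate_survival_cohort(1, genes, 2), ">= 2")
  expect_error(simulate_survival_cohort(60, genes, 0), "> 0")
})

test_that("null survival cohort rejects at the nominal log-rank level", {
  rej <- vapply(1:100, function(s) {
    sc <- simulate_survival_cohort(60, paste0("G", 1:4), hazard_ratio = 1,
                                   censor_rate = 0.2, seed = s)
    km <- km_logrank(sc$os_months, sc$event, sc$truth$cluster)
    km$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.0)
  expect_lte(mean(rej), 0.12)         # ~0.05 within binomial noise at 100 reps
})
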