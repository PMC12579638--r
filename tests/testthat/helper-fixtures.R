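# shared fixture builders; everything is generated in code at test time

# small planted-signal cohort used by several suites
small_cohort <- function(seed = 7, n_per_group = 10, n_features = 100,
                         n_disc = 6, shift = 80, noise = 40,
                         missing = 0.15) {
  cfg <- simulation_config(
    n_samples_per_group = n_per_group, n_cell_types = 3,
    n_lr_pairs = n_features, n_discriminative = n_disc,
    rank_shift = shift, method_noise_sd = noise,
    missing_rate = missing, seed = seed)
  simulate_interaction_cohort(cfg)
}

# separable two-class Gaussian data for the discriminant suites
gaussian_classes <- function(n = 40, d = 10, sep = 5, seed = 1) {
  set.seed(seed)
  y <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * d), n, d)
  X[y == "B", 1] <- X[y == "B", 1] + sep
  colnames(X) <- paste0("f", seq_len(d))
  list(X = X, y = y)
}

# tiny hand-built interaction records (only the columns the matrix
# assembly needs)
hand_records <- function() {
  list(
    s1 = data.frame(feature_id = c("a", "b"), mean_rank = c(10, 20),
                    stringsAsFactors = FALSE),
    s2 = data.frame(feature_id = c("b", "c"), mean_rank = c(30, 40),
                    stringsAsFactors = FALSE))
}
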