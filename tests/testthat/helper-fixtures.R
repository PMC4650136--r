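# Shared fixtures, built in code.

# Small deterministic synthetic data set (M8 truth, default grid).
fixture_dataset <- function(seed = 11, variant = 8, ...) {
  generate_dataset(synth_config(variant = variant, seed = seed, ...))
}

# Tiny hand-rolled count table: 2 genes x 3 times x 3 replicates with
# simple numbers, for brute-force likelihood oracles.
tiny_counts <- function() {
  df <- expand.grid(replicate = 1:3, time_h = c(0, 6, 24),
                    gene = c("STAT3", "FOXP3"), stringsAsFactors = FALSE)
  df$count <- c(101, 95, 110, 150, 160, 140, 170, 180, 175,
                12, 9, 14, 30, 25, 28, 55, 60, 52)
  df$library_size <- rep(c(1.0e6, 1.1e6, 0.9e6), 6)
  df$dispersion <- rep(rep(c(0.05, 0.1, 0.2), each = 3), 2)
  th17_counts(df)
}

# A trajectory at the reference parameterization for a given variant.
fixture_traj <- function(variant = 8, times = c(0, 6, 24),
                         init = th17_init(stat3_mrna = 0.1,
                                          rorgt_mrna = 0.01,
                                          foxp3_mrna = 0.02)) {
  v <- build_variant(variant)
  simulate_th17(v, restrict_theta(reference_theta(), v), init,
                times = times)
}

# Gaussian plug-in log-likelihood: with the standard normal prior on
# eta, the beta = 1 posterior is N(mu/2, 1/2) in each coordinate.
gaussian_loglik <- function(mu = 1, d = 2) {
  function(eta) sum(dnorm(eta, mu, 1, log = TRUE))
}

# Conjugate normal-normal toy: prior eta ~ N(0,1), y_i ~ N(eta, sigma^2)
# => closed-form log marginal likelihood.
conjugate_toy <- function(y, sigma) {
  loglik <- function(eta) sum(dnorm(y, eta, sigma, log = TRUE))
  n <- length(y)
  v_post <- 1 / (1 + n / sigma^2)
  log_z <- sum(dnorm(y, 0, sigma, log = TRUE)) + 0.5 * log(v_post) +
    0.5 * (sum(y) / sigma^2)^2 * v_post
  list(loglik = loglik, log_z = log_z)
}
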