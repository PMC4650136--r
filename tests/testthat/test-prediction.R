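make_small_fit <- function(seed = 12, protein = FALSE, variant = 8) {
  ds <- fixture_dataset(seed = seed, variant = variant)
  fit_th17(ds$counts, variant,
           protein = if (protein) ds$protein,
           settings = sampler_settings(n_beta = 4, n_iter = 400,
                                       thin = 10, n_samplers = 2),
           seed = 7)
}

test_that("predictive bands are ordered and live on the observed span", {
  fit <- make_small_fit()
  band <- posterior_predictive(fit, grid = seq(0, 72, by = 8),
                               max_draws = 60, seed = 2)
  expect_true(all(band$q05 <= band$q50 & band$q50 <= band$q95))
  expect_setequal(unique(band$gene), c("STAT3", "RORGT", "FOXP3"))
  expect_error(posterior_predictive(fit, grid = c(0, 80)), "outside")
})

test_that("single-draw predictive quantiles match the NB quantile function", {
  ds <- fixture_dataset(seed = 15)
  truth_eta <- matrix(log(ds$truth$theta), nrow = 1)
  draws <- truth_eta[rep(1, 3000), , drop = FALSE]
  sc <- prediction_scale(ds$counts)
  t_obs <- 24
  band <- predictive_band(draws, build_variant(8), ds$counts,
                          th17_init(counts = ds$counts),
                          grid = c(t_obs), probs = c(0.05, 0.5, 0.95),
                          max_draws = 3000, seed = 4)
  tr <- simulate_th17(build_variant(8), ds$truth$theta,
                      th17_init(counts = ds$counts),
                      times = sort(unique(c(0, t_obs))))
  for (g in c("STAT3", "RORGT", "FOXP3")) {
    x <- traj_at(tr, t_obs, th17ti:::gene_to_state(g))[1, 1]
    phi <- sc$phi_fun[[g]](t_obs)
    q_oracle <- qnbinom(c(0.05, 0.5, 0.95), size = 1 / phi,
                        mu = sc$lbar * x) / sc$lbar
    got <- unlist(band[band$gene == g, c("q05", "q50", "q95")])
    expect_equal(got, q_oracle, tolerance = 0.05, ignore_attr = TRUE,
                 label = sprintf("%s quantiles", g))
  }
})

test_that("bands collapse onto the trajectory as dispersion vanishes and widen with it", {
  fit <- make_small_fit()
  tight <- posterior_predictive(fit, grid = c(12, 48), max_draws = 40,
                                seed = 3, phi_multiplier = 1e-8)
  wide <- posterior_predictive(fit, grid = c(12, 48), max_draws = 40,
                               seed = 3, phi_multiplier = 5)
  base <- posterior_predictive(fit, grid = c(12, 48), max_draws = 40,
                               seed = 3)
  # with larger dispersion, bands are wider in expectation
  expect_gt(mean(wide$q95 - wide$q05), mean(base$q95 - base$q05))
  expect_gt(mean(base$q95 - base$q05), mean(tight$q95 - tight$q05))
})

test_that("a basal-only variant predicts a dose-invariant FOXP3 response", {
  fit4 <- make_small_fit(seed = 16, variant = 4)
  dr <- predict_dose_response(fit4, max_draws = 20)
  expect_equal(diff(range(dr$mean)), 0, tolerance = 1e-9)
  expect_equal(diff(range(dr$q50)), 0, tolerance = 1e-9)
})

test_that("TGFb-driven variants predict nondecreasing dose-response per draw", {
  ds <- fixture_dataset(seed = 17)
  v <- build_variant(8)
  set.seed(31)
  doses <- c(1/16, 1/8, 1/4, 1/2, 1)
  for (i in 1:10) {
    theta <- exp(rnorm(17, sd = 0.5))   # theta14 present and positive
    f <- fstar_at_doses(v, theta, th17_init(counts = ds$counts), doses,
                        method = "per_dose")
    expect_true(all(diff(f) >= -(1e-8 * max(abs(f)) + 1e-9)))
  }
  # and the reference dose reproduces the training condition
  theta <- ds$truth$theta
  tr <- simulate_th17(v, theta, th17_init(counts = ds$counts),
                      cytokine_input(), times = c(0, 72))
  f <- fstar_at_doses(v, theta, th17_init(counts = ds$counts), 1,
                      method = "per_dose")
  expect_equal(f, tr$states[2, "foxp3_prot_star"], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("predictive band covers held-out replicates at roughly nominal rate", {
  ds <- fixture_dataset(seed = 18)
  truth_eta <- matrix(log(ds$truth$theta), nrow = 1)
  draws <- truth_eta[rep(1, 500), , drop = FALSE]
  band <- predictive_band(draws, build_variant(8), ds$counts,
                          th17_init(counts = ds$counts),
                          grid = ds$counts$times, max_draws = 500,
                          seed = 9)
  d <- ds$counts$df
  d$scaled <- d$count / (ds$counts$count_scale * d$library_size)
  hits <- vapply(seq_len(nrow(d)), function(r) {
    b <- band[band$gene == d$gene[r] & band$time_h == d$time_h[r], ]
    d$scaled[r] >= b$q05 && d$scaled[r] <= b$q95
  }, logical(1))
  expect_gte(mean(hits), 0.78)
  expect_lte(mean(hits), 1.0)
})
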