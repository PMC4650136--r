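test_that("NB log pmf matches the reference implementation over a grid", {
  grid <- expand.grid(y = c(0, 1, 7, 150, 1e6), mu = c(0.3, 5, 2e5),
                      phi = c(0.01, 0.5, 3))
  expect_equal(
    nb_logpmf(grid$y, grid$mu, grid$phi),
    dnbinom(grid$y, size = 1 / grid$phi, mu = grid$mu, log = TRUE),
    tolerance = 1e-10)
  # stays finite even at extreme counts
  expect_true(is.finite(nb_logpmf(1e7, 1e7, 0.2)))
})

test_that("NB log pmf approaches Poisson as dispersion vanishes", {
  y <- 0:20
  expect_equal(nb_logpmf(y, mu = 3, phi = 1e-8),
               dpois(y, 3, log = TRUE), tolerance = 1e-5)
})

test_that("NB input domain is enforced and mu = 0 behaves as a point mass", {
  expect_error(nb_logpmf(-1, 5, 0.1), "nonnegative integers")
  expect_error(nb_logpmf(2.5, 5, 0.1), "nonnegative integers")
  expect_error(nb_logpmf(2, 5, 0), "positive")
  expect_error(nb_logpmf(2, -5, 0.1), "nonnegative")
  expect_equal(nb_logpmf(0, 0, 0.3), 0, tolerance = 1e-10)
  expect_lt(nb_logpmf(5, 0, 0.3), -100)
})

test_that("log prior is standard normal in log space", {
  d <- 7
  expect_equal(log_prior(rep(1, d)), -d * log(sqrt(2 * pi)))
  theta <- exp(c(-0.4, 1.2, 0.3))
  expect_equal(log_prior(theta), sum(dnorm(log(theta), log = TRUE)))
  expect_identical(log_prior(c(1, 0, 2)), -Inf)
  expect_identical(log_prior(c(1, -3)), -Inf)
})

test_that("count likelihood equals the brute-force term-by-term sum", {
  counts <- tiny_counts()
  tr <- fixture_traj(8, times = c(0, 6, 24))
  # oracle: walk the 18 (gene, time, replicate) cells one by one
  map <- c(STAT3 = "stat3_mrna", FOXP3 = "foxp3_mrna")
  brute <- 0
  for (r in seq_len(nrow(counts$df))) {
    row <- counts$df[r, ]
    x <- tr$states[match(row$time_h, tr$times), map[[row$gene]]]
    brute <- brute + dnbinom(row$count, size = 1 / row$dispersion,
                             mu = row$library_size * x, log = TRUE)
  }
  expect_equal(count_loglik(counts, tr), brute, tolerance = 1e-10)
})

test_that("a single observation reduces to one NB term", {
  df <- data.frame(gene = "STAT3", time_h = 0, replicate = 1, count = 42,
                   library_size = 500, dispersion = 0.2)
  tr <- fixture_traj(8, times = c(0, 6))
  expect_equal(count_loglik(th17_counts(df), tr),
               nb_logpmf(42, 500 * tr$states[1, "stat3_mrna"], 0.2))
})

test_that("likelihood is exchangeable in replicates and consistent under relabeling", {
  counts <- tiny_counts()
  tr <- fixture_traj(8, times = c(0, 6, 24))
  base <- count_loglik(counts, tr)
  shuf <- counts$df
  shuf$replicate <- ifelse(shuf$replicate == 1, 3,
                           ifelse(shuf$replicate == 3, 1, 2))
  expect_equal(count_loglik(th17_counts(shuf), tr), base)
  # relabel genes and adapt the map consistently
  ren <- counts$df
  ren$gene <- c(STAT3 = "geneA", FOXP3 = "geneB")[ren$gene]
  expect_equal(
    count_loglik(th17_counts(ren), tr,
                 gene_map = c(geneA = "stat3_mrna",
                              geneB = "foxp3_mrna")),
    base)
  expect_error(count_loglik(th17_counts(ren), tr), "no state mapping")
})

test_that("likelihood is invariant to rescaling library sizes against abundances", {
  counts <- tiny_counts()
  tr <- fixture_traj(8, times = c(0, 6, 24))
  c_scale <- 37.5
  scaled <- counts$df
  scaled$library_size <- scaled$library_size * c_scale
  tr_scaled <- tr
  tr_scaled$states <- tr$states / c_scale
  expect_equal(count_loglik(th17_counts(scaled), tr_scaled),
               count_loglik(counts, tr), tolerance = 1e-9)
})

test_that("missing replicates are skipped, not imputed", {
  counts <- tiny_counts()
  drop_idx <- c(2, 17)
  with_na <- counts$df
  with_na$count[drop_idx] <- NA
  tr <- fixture_traj(8, times = c(0, 6, 24))
  expect_equal(count_loglik(th17_counts(with_na), tr),
               count_loglik(th17_counts(counts$df[-drop_idx, ]), tr))
})

test_that("prediction scale averages library sizes and hits dispersion knots", {
  counts <- tiny_counts()
  sc <- prediction_scale(counts)
  expect_equal(sc$lbar, mean(rep(c(1.0e6, 1.1e6, 0.9e6), 3)))
  for (g in counts$genes) {
    dg <- counts$df[counts$df$gene == g, ]
    dg <- dg[!duplicated(dg$time_h), ]
    expect_equal(sc$phi_fun[[g]](dg$time_h), dg$dispersion)
  }
})

test_that("interpolated likelihood peaks at the model trajectory", {
  # small dispersions: the NB mode then coincides with the mean to
  # within the grid resolution
  df <- tiny_counts()$df
  df$dispersion <- 1e-4
  counts <- th17_counts(df)
  tr <- fixture_traj(8, times = c(0, 6, 24))
  sc <- prediction_scale(counts)
  t_q <- 13.7
  x <- c(STAT3 = unname(traj_at(tr, t_q, "stat3_mrna")[1, 1]),
         FOXP3 = unname(traj_at(tr, t_q, "foxp3_mrna")[1, 1]))
  ll_at <- function(f) interpolated_loglik(x * f, tr, sc, t_q)
  factors <- seq(0.5, 1.6, by = 0.05)
  lls <- vapply(factors, ll_at, numeric(1))
  expect_equal(factors[which.max(lls)], 1, tolerance = 0.051)
  # monotone decrease away from the trajectory
  expect_true(all(diff(lls[factors >= 1]) < 0))
  expect_true(all(diff(lls[factors <= 1]) > 0))
  expect_error(interpolated_loglik(x, tr, sc, 25), "within the observed")
})

test_that("protein likelihood matches the Gaussian form and its corner cases", {
  prot <- th17_protein(data.frame(dose_ng_ml = c(1/16, 1/8, 1/4, 1/2, 1),
                                  mean_percent = c(2, 4, 8, 16, 30),
                                  sd_percent = c(1, 1, 2, 2, 3)))
  v <- build_variant(8)
  th <- restrict_theta(reference_theta(), v)
  f <- fstar_at_doses(v, th, th17_init(stat3_mrna = 1), prot$df$dose_ng_ml,
                      method = "per_dose")
  # zero residuals: likelihood reduces to the normalizing constants
  exact <- th17_protein(data.frame(dose_ng_ml = prot$df$dose_ng_ml,
                                   mean_percent = 25 * f,
                                   sd_percent = prot$df$sd_percent))
  expect_equal(protein_loglik(exact, v, th, th17_init(stat3_mrna = 1),
                              s = 25, method = "per_dose"),
               -sum(log(prot$df$sd_percent * sqrt(2 * pi))))
  # general case equals a hand-written Gaussian sum
  expect_equal(protein_loglik(prot, v, th, th17_init(stat3_mrna = 1),
                              s = 25, method = "per_dose"),
               sum(dnorm(prot$df$mean_percent, 25 * f,
                         prot$df$sd_percent, log = TRUE)))
})

test_that("dose superposition equals per-dose integration across variants", {
  set.seed(77)
  for (vid in c(1, 4, 8, 12)) {
    v <- build_variant(vid)
    theta <- exp(rnorm(n_free_parameters(v)) * 0.5)
    init <- th17_init(stat3_mrna = 0.8, rorgt_mrna = 0.01,
                      foxp3_mrna = 0.03)
    doses <- c(1/16, 1/8, 1/4, 1/2, 1)
    expect_equal(
      fstar_at_doses(v, theta, init, doses, method = "superposition"),
      fstar_at_doses(v, theta, init, doses, method = "per_dose"),
      tolerance = 1e-6, label = sprintf("M%d", vid))
  }
})

test_that("joint likelihood composes count and protein parts", {
  ds <- fixture_dataset(seed = 30)
  v <- build_variant(8)
  init <- th17_init(counts = ds$counts)
  tr <- simulate_th17(v, ds$truth$theta, init, times = ds$counts$times)
  ll_c <- count_loglik(ds$counts, tr)
  ll_p <- protein_loglik(ds$protein, v, ds$truth$theta, init, s = 25)
  expect_equal(joint_loglik(ds$counts, tr), ll_c)
  expect_equal(joint_loglik(ds$counts, tr, ds$protein, s = 25),
               ll_c + ll_p)
})

test_that("count and protein tables survive a TSV round trip", {
  ds <- fixture_dataset(seed = 31)
  cpath <- withr::local_tempfile(fileext = ".tsv")
  ppath <- withr::local_tempfile(fileext = ".tsv")
  write_counts(ds$counts, cpath, header = c("fixture", "seed: 31"))
  write_protein(ds$protein, ppath)
  expect_equal(read_counts(cpath)$df, ds$counts$df, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(read_protein(ppath)$df, ds$protein$df, tolerance = 1e-12,
               ignore_attr = TRUE)
})
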