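test_that("cytokine closed form matches numeric integration of the conversion ODEs", {
  # independent oracle: integrate the extracellular/intracellular pair
  # directly with an R right-hand side
  oracle <- function(t, rate, added, ref) {
    rhs <- function(t, y, p) list(c(-p * y[1], p * y[1]))
    out <- deSolve::ode(c(added / ref, 0), c(0, t), rhs, rate,
                        method = "lsoda", rtol = 1e-12, atol = 1e-14)
    unname(out[2, 3])
  }
  for (case in list(c(24, 0.1, 1, 1), c(7.5, 0.35, 20, 20),
                    c(72, 0.02, 0.5, 1))) {
    expect_equal(
      cytokine_analytic(case[1], case[2], case[3], case[4]),
      oracle(case[1], case[2], case[3], case[4]), tolerance = 1e-8)
  }
  expect_identical(cytokine_analytic(0, 0.3, 20, 20), 0)
  expect_equal(cytokine_analytic(1e6, 0.3, 20, 20), 1)
  expect_error(cytokine_analytic(1, 0.3, 20, 0), "positive")
  expect_error(cytokine_analytic(-1, 0.3, 20, 20), "nonnegative")
})

test_that("right-hand side matches the network structure at corner states", {
  zero <- setNames(numeric(6), c("stat3_mrna", "stat3_prot",
                                 "stat3_prot_star", "rorgt_mrna",
                                 "foxp3_mrna", "foxp3_prot_star"))
  inp <- cytokine_input()
  # M5: no basal FOXP3 term, so FOXP3 mRNA cannot be produced from
  # nothing at t = 0 (TGFb_int = 0)
  v5 <- build_variant(5)
  th5 <- expand_theta(restrict_theta(reference_theta(), v5), v5)
  expect_identical(th17_rhs(0, zero, th5, inp)[["foxp3_mrna"]], 0)
  # M1: basal term alone drives FOXP3 mRNA
  v1 <- build_variant(1)
  th1 <- expand_theta(restrict_theta(reference_theta(), v1), v1)
  expect_identical(th17_rhs(0, zero, th1, inp)[["foxp3_mrna"]],
                   th1[["theta13"]])
  # no basal RORgt production: zero state, zero TGFb => no RORgt change
  expect_identical(th17_rhs(0, zero, th1, inp)[["rorgt_mrna"]], 0)
})

test_that("STAT3 module converges to its IL6-free steady state", {
  # oracle: set the three STAT3 derivatives to zero with IL6_int = 0 and
  # solve the linear system
  v <- build_variant(1)
  th <- expand_theta(restrict_theta(reference_theta(), v), v)
  a <- matrix(c(-th[4], 0, th[3],
                th[5], -th[7], 0,
                0, 0, -th[8]), 3, 3, byrow = TRUE)
  ss <- solve(a, c(-th[2], 0, 0))
  expect_equal(ss, c(th[2] / th[4], th[5] * th[2] / (th[4] * th[7]), 0),
               ignore_attr = TRUE)
  tr <- simulate_th17(v, restrict_theta(th, v),
                      th17_init(stat3_mrna = 0.3),
                      cytokine_input(il6_added = 0),
                      times = c(0, 500, 1000))
  expect_equal(unname(tr$states[3, c("stat3_mrna", "stat3_prot",
                                     "stat3_prot_star")]),
               ss, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("integrated cytokine states agree with the closed forms", {
  v <- build_variant(8)
  th <- restrict_theta(reference_theta(), v)
  times <- seq(0, 72, by = 0.5)
  tr <- simulate_th17(v, th, th17_init(stat3_mrna = 1), times = times,
                      cytokines = "ode")
  expect_lt(max(abs(tr$states[, "il6_int"] -
                    cytokine_analytic(times, th[["theta1"]], 20, 20))),
            1e-6)
  expect_lt(max(abs(tr$states[, "tgfb_int"] -
                    cytokine_analytic(times, th[["theta9"]], 1, 1))),
            1e-6)
})

test_that("cytokine mass is conserved along integrated trajectories", {
  tr <- fixture_traj(12, times = seq(0, 72, by = 3))
  tr <- simulate_th17(tr$variant, restrict_theta(tr$theta_full,
                                                 tr$variant),
                      tr$init, times = seq(0, 72, by = 3),
                      cytokines = "ode")
  il6_total <- tr$states[, "il6_ext"] + tr$states[, "il6_int"]
  tgfb_total <- tr$states[, "tgfb_ext"] + tr$states[, "tgfb_int"]
  expect_lt(max(abs(il6_total - il6_total[1])), 1e-7)
  expect_lt(max(abs(tgfb_total - tgfb_total[1])), 1e-7)
})

test_that("doubling the TGFb dose doubles the intracellular level at all times", {
  v <- build_variant(8)
  th <- restrict_theta(reference_theta(), v)
  t1 <- simulate_th17(v, th, input = cytokine_input(tgfb_added = 1),
                      times = 0:72)
  t2 <- simulate_th17(v, th, input = cytokine_input(tgfb_added = 2),
                      times = 0:72)
  expect_equal(t2$states[, "tgfb_int"], 2 * t1$states[, "tgfb_int"],
               tolerance = 1e-10)
})

test_that("RORgt mRNA decays monotonically without its activation term", {
  v <- build_variant(1)
  th <- restrict_theta(reference_theta(), v)
  th[["theta10"]] <- 1e-12   # activation switched off in the limit
  tr <- simulate_th17(v, th, th17_init(stat3_mrna = 1, rorgt_mrna = 0.5),
                      times = seq(0, 48, by = 2))
  expect_true(all(diff(tr$states[, "rorgt_mrna"]) < 0))
})

test_that("states stay nonnegative across prior draws", {
  set.seed(401)
  v <- build_variant(12)
  n_ok <- 0
  for (i in 1:25) {
    theta <- exp(rnorm(length(v$active)))
    tr <- simulate_th17(v, theta,
      th17_init(stat3_mrna = 0.5, rorgt_mrna = 0.01, foxp3_mrna = 0.05),
      times = seq(0, 72, by = 6))
    if (!tr$ok) next
    n_ok <- n_ok + 1
    expect_gt(min(tr$states), -1e-8)
  }
  expect_gt(n_ok, 15)   # most prior draws integrate
})

test_that("the full model collapses onto nested variants in the limit", {
  v12 <- build_variant(12)
  v8 <- build_variant(8)
  th8 <- restrict_theta(reference_theta(), v8)
  th12 <- restrict_theta(reference_theta(), v12)
  th12[["theta13"]] <- 1e-10  # basal induction to its limiting value
  init <- th17_init(stat3_mrna = 1, rorgt_mrna = 0.01, foxp3_mrna = 0.05)
  tr12 <- simulate_th17(v12, th12, init, times = seq(0, 72, by = 6))
  tr8 <- simulate_th17(v8, th8, init, times = seq(0, 72, by = 6))
  expect_equal(tr12$states, tr8$states, tolerance = 1e-6)
})

test_that("failed integrations are flagged, never silent NaN", {
  v <- build_variant(1)
  th <- restrict_theta(reference_theta(), v)
  # an explosive autoregulatory loop: production vastly exceeds decay
  th[c("theta3", "theta5", "theta6")] <- c(500, 500, 200)
  tr <- simulate_th17(v, th, times = c(0, 36, 72))
  expect_false(tr$ok)
  expect_true(all(is.na(tr$states)))
  expect_error(traj_at(tr, 10), "failed")
  expect_identical(count_loglik(tiny_counts(), tr), -Inf)
})

test_that("trajectory queries interpolate and respect the span", {
  tr <- fixture_traj(8, times = seq(0, 24, by = 2))
  expect_equal(traj_at(tr, c(0, 24), "rorgt_mrna")[, 1],
               tr$states[c(1, 13), "rorgt_mrna"], ignore_attr = TRUE)
  expect_error(traj_at(tr, 25), "outside")
  df <- as.data.frame(tr)
  expect_identical(names(df), c("time_h", "species", "value"))
  expect_identical(nrow(df), 13L * 10L)
})
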