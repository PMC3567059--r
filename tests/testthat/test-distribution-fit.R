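test_that("Poisson GOF accepts Poisson data and pools small bins", {
  set.seed(1)
  x <- rpois(500, 9.3)
  fit <- poisson_gof(x)
  expect_equal(fit$lambda_mle, mean(x))
  expect_gt(fit$p_value, 0.001)
  nb <- nrow(fit$table)
  expect_gte(fit$table$expected[1], 5)     # pooled bottom bin
  expect_gte(fit$table$expected[nb], 5)    # pooled open top bin
  expect_equal(fit$dof, nrow(fit$table) - 2L)
  expect_gte(fit$chi2, 0)
  expect_error(poisson_gof(c(0.5, 1)), "integers")
  expect_error(poisson_gof(rep(1L, 50)), "3 bins")
})

test_that("Poisson GOF p-values are calibrated and have power", {
  set.seed(2)
  pv <- replicate(400, poisson_gof(rpois(108, 9.315))$p_value)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.035)
  # rejects a geometric law of equal mean most of the time
  pw <- replicate(200, poisson_gof(rgeom(108, 1 / 10.3))$p_value < 0.05)
  expect_gt(mean(pw), 0.8)
})

test_that("discrete power-law sampler and pmf agree with an oracle sampler", {
  x1 <- rpowerlaw(20000, 2.5, seed = 3)
  set.seed(4)
  x2 <- oracle_rpowerlaw(20000, 2.5)
  expect_gt(ks_two_sample(x1, x2)$p_value, 0.01)
  expect_equal(sum(dpowerlaw(1:100000, 2.5)), 1, tolerance = 1e-4)
  expect_equal(ppowerlaw(10, 2.5), sum(dpowerlaw(1:10, 2.5)))
})

test_that("power-law MLE recovers alpha and kmin on exact tails", {
  # plug-in: exact proportions p(k) ~ k^-3
  k <- 1:1000
  n_each <- round(1e5 * dpowerlaw(k, 3))
  x <- rep(k, n_each)
  fit <- fit_power_law(x, n_bootstrap = 0)
  expect_lt(fit$ks_D, 0.01)
  expect_lt(abs(fit$alpha - 3), 0.05)

  x <- rpowerlaw(5000, 2.5, k_min = 1, seed = 5)
  fit <- fit_power_law(x, n_bootstrap = 100, seed = 6)
  expect_gt(fit$alpha, 2.4); expect_lt(fit$alpha, 2.6)
  expect_gt(fit$p_value, 0.1)
})

test_that("power-law fit rejects Poisson degrees", {
  x <- rpois(5000, 9)
  fit <- fit_power_law(x, n_bootstrap = 100, seed = 7)
  expect_lt(fit$p_value, 0.05)
})

test_that("cross-check: MLE matches igraph's independent plfit estimate", {
  x <- rpowerlaw(3000, 2.3, seed = 8)
  ours <- fit_power_law(x, n_bootstrap = 0)
  theirs <- igraph::fit_power_law(x, xmin = ours$k_min,
                                  implementation = "plfit")
  expect_lt(abs(ours$alpha - theirs$alpha), 0.05)
})

test_that("potential regression inverts noiseless log-linear data", {
  d <- list(k = c(1, 2, 4, 8), p = 0.5 * c(1, 2, 4, 8) ^ -2)
  fit <- suppressWarnings(potential_regression(d))
  expect_equal(fit$gamma, 2)
  expect_equal(fit$C, 0.5)
  expect_equal(fit$r2_adjusted, 1)

  d$p[2] <- d$p[2] * 1.5
  expect_lt(potential_regression(d)$r2_adjusted, 1)

  # Poisson pmf is curved in log-log space
  d2 <- list(k = 4:15, p = dpois(4:15, 9))
  expect_lt(potential_regression(d2)$r2_adjusted, 0.9)
  expect_error(potential_regression(list(k = 1:2, p = c(0.5, 0.5))),
               "3 support points")
})

test_that("potential regression is scale-equivariant", {
  set.seed(9)
  d <- list(k = 1:12, p = dpowerlaw(1:12, 2.2) * exp(rnorm(12, 0, 0.1)))
  f1 <- potential_regression(d)
  d2 <- list(k = d$k, p = 10 * d$p)
  f2 <- potential_regression(d2)
  expect_equal(f2$gamma, f1$gamma)
  expect_equal(f2$C, 10 * f1$C)
  expect_equal(f2$r2_adjusted, f1$r2_adjusted)
})

test_that("cutoff law is proper, sub-power-law, and has the right limit", {
  expect_equal(sum(powerlaw_cutoff_pdf(1:2000, 2, 10)), 1, tolerance = 1e-8)
  k <- 1:50
  ratio <- powerlaw_cutoff_pdf(2 * k, 2.5, 20) / powerlaw_cutoff_pdf(k, 2.5, 20)
  expect_true(all(ratio < 2 ^ -2.5))
  diffs <- abs(powerlaw_cutoff_pdf(1:100, 2.5, 1e9) - dpowerlaw(1:100, 2.5))
  expect_lt(max(diffs), 1e-6)
  expect_error(powerlaw_cutoff_pdf(1:5, -1, 10), "alpha")
})

test_that("two-sample KS separates equal and different Poisson laws", {
  x <- rpois(400, 9.3)
  same <- ks_two_sample(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)
  set.seed(10)
  null_ok <- replicate(100, ks_two_sample(rpois(400, 9.3),
                                          rpois(400, 9.3))$p_value > 0.05)
  expect_gte(mean(null_ok), 0.9)
  alt <- replicate(50, ks_two_sample(rpois(400, 9.3),
                                     rpois(400, 5))$p_value < 0.01)
  expect_gte(mean(alt), 0.99)
})
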