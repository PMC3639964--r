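test_that("priors follow the study protocol", {
  pr <- make_priors()
  expect_equal(pr$density("phi", 0.5), 1)
  expect_equal(pr$density("phi", 1.5), 0)
  expect_equal(pr$density("sigma", 5), 0.1)
  expect_equal(pr$density("sigma", 11), 0)
  expect_equal(pr$sigma, c(0, 10))
})

test_that("two-occasion studies return the saturated product phi * p", {
  y <- rbind(matrix(c(1L, 1L), 10, 2, byrow = TRUE),
             matrix(c(1L, 0L), 30, 2, byrow = TRUE),
             matrix(c(0L, 1L), 5, 2, byrow = TRUE))
  ch <- capture_history(y)
  fit <- fit_cjs_mle(ch)
  expect_equal(unname(fit$estimate["phi_x_p"]), 10 / 40)
})

test_that("constant-p MLE matches a grid-search oracle", {
  ch <- simulate_dataset(scenario_spec("symmetric", n_occasions = 6,
                                       n_new_per_occasion = 15), seed = 21)
  grid <- seq(0.01, 0.99, by = 0.01)
  ll <- outer(grid, grid, Vectorize(function(a, b) cjs_loglik(ch, a, b)))
  best <- arrayInd(which.max(ll), dim(ll))
  fit <- fit_cjs_mle(ch, "constant_p")
  expect_lt(abs(fit$estimate["phi"] - grid[best[1]]), 0.011)
  expect_lt(abs(fit$estimate["p"] - grid[best[2]]), 0.011)
  expect_gte(fit$loglik, max(ll) - 1e-6)
})

test_that("MLE recovers generating parameters at study scale", {
  ch <- simulate_dataset(homogeneous_spec(0.4), seed = 31)
  fit <- fit_cjs_mle(ch, "constant_p")
  expect_lt(abs(fit$estimate["phi"] - 0.7), 3 * fit$se["phi"] + 0.01)
  expect_lt(abs(fit$estimate["p"] - 0.4), 3 * fit$se["p"] + 0.01)
})

test_that("homogeneous data drive the fitted heterogeneity to the boundary", {
  res <- vapply(1:8, function(r) {
    ch <- simulate_dataset(homogeneous_spec(0.4, n_occasions = 10,
                                            n_new_per_occasion = 40),
                           seed = 300 + r)
    fit <- fit_cjs_mle(ch, "re_p")
    fit$boundary || fit$estimate["sigma"] < 0.3
  }, logical(1))
  expect_gt(mean(res), 0.5)
})

test_that("MCMC respects the kept-sample arithmetic and protocol", {
  sp <- scenario_spec("symmetric", n_occasions = 8, n_new_per_occasion = 10)
  ch <- simulate_dataset(sp, seed = 41)
  fit <- fit_cjs_mcmc(ch, "re_p", chains = 1, iter = 30000, burnin = 20000,
                      thin = 10, seed = 5)
  expect_equal(fit$n_kept, 1000)
  expect_equal(nrow(fit$samples[[1]]), 1000)
  expect_true(all(fit$summary$q2.5 <= fit$summary$q50 &
                  fit$summary$q50 <= fit$summary$q97.5))
  expect_error(fit_cjs_mcmc(ch, iter = 100, burnin = 200), "exceed")
  expect_error(fit_cjs_mcmc(ch, iter = 105, burnin = 100, thin = 10),
               "zero kept")
})

test_that("posterior concentrates near 1 for all-detected histories", {
  ch <- capture_history(matrix(1L, 25, 15))
  fit <- fit_cjs_mcmc(ch, "constant_p", iter = 4000, burnin = 2000,
                      thin = 2, seed = 6)
  expect_gt(fit$summary$q2.5[fit$summary$parameter == "phi"], 0.85)
  expect_gt(fit$summary$q2.5[fit$summary$parameter == "p"], 0.85)
})

test_that("posterior mean agrees with the MLE under flat priors", {
  ch <- simulate_dataset(scenario_spec("symmetric"), seed = 51)
  mle <- fit_cjs_mle(ch, "constant_p")
  mc <- fit_cjs_mcmc(ch, "constant_p", iter = 6000, burnin = 2000, thin = 2,
                     seed = 7)
  for (par in c("phi", "p"))
    expect_lt(abs(mc$estimate[par] - mle$estimate[par]),
              3 * mle$se[par])
})

test_that("chain-length halving leaves posterior means stable", {
  ch <- simulate_dataset(scenario_spec("symmetric", n_occasions = 10,
                                       n_new_per_occasion = 25), seed = 61)
  full <- fit_cjs_mcmc(ch, "constant_p", iter = 8000, burnin = 2000,
                       thin = 2, seed = 8)
  half <- fit_cjs_mcmc(ch, "constant_p", iter = 5000, burnin = 2000,
                       thin = 2, seed = 9)
  # differences bounded by a few posterior SDs over the kept-sample size
  for (par in c("phi", "p")) {
    sd_p <- full$summary$sd[full$summary$parameter == par]
    expect_lt(abs(full$estimate[par] - half$estimate[par]), 6 * sd_p /
                sqrt(1000))
  }
})

test_that("BGR diagnostic behaves at its analytic extremes", {
  set.seed(10)
  x <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("a", "b")))
  r_same <- bgr_diagnostic(list(x, x, x))
  expect_true(all(abs(r_same - 1) < 0.01))
  far <- x + 100
  r_far <- bgr_diagnostic(list(x, far))
  expect_true(all(r_far > 10))
  expect_error(bgr_diagnostic(list(x)), "at least 2 chains")
  expect_error(bgr_diagnostic(list(x, x[1:10, ])), "identical dimensions")
})

test_that("parameter point estimates flow through coef and summary", {
  ch <- simulate_dataset(scenario_spec("symmetric", n_occasions = 6,
                                       n_new_per_occasion = 10), seed = 71)
  fit <- fit_cjs_mle(ch, "re_p")
  expect_named(coef(fit), c("phi", "p_mean", "sigma"))
  s <- summary(fit)
  expect_equal(s$parameter, c("phi", "p_mean", "sigma"))
  expect_equal(s$mean, unname(fit$estimate))
})
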