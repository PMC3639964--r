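test_that("single-history likelihoods match hand enumeration", {
  expect_equal(exp(cjs_history_loglik(c(1, 0, 1), 1, 0.7, 0.4)),
               0.7 * 0.6 * 0.7 * 0.4, tolerance = 1e-12)
  expect_equal(exp(cjs_history_loglik(c(1, 1), 1, 0.7, 0.4)), 0.28,
               tolerance = 1e-12)
  expect_equal(exp(cjs_history_loglik(c(1, 0), 1, 0.7, 0.4)),
               0.7 * 0.6 + 0.3, tolerance = 1e-12)
})

test_that("history input errors are caught", {
  expect_no_error(cjs_history_loglik(c(0, 1, 0), 2, 0.7, 0.4))
  expect_error(cjs_history_loglik(c(0, 1, 0), 1, 0.7, 0.4),
               "first capture")
  expect_error(cjs_history_loglik(c(1, 1, 0), 2, 0.7, 0.4),
               "before first capture")
  expect_error(cjs_history_loglik(c(1, 0, 1), 5, 0.7, 0.4), "out of range")
})

test_that("forward recursion equals latent-path enumeration, K <= 6", {
  for (K in c(4, 6)) {
    for (phi in c(0.3, 0.7)) {
      p <- 0.45
      pats <- all_histories(K)
      for (r in seq_len(nrow(pats))) {
        y <- pats[r, ]
        expect_equal(exp(cjs_history_loglik(y, 1, phi, p)),
                     enum_history_prob(y, 1, phi, p), tolerance = 1e-12)
      }
      # patterns with a later first capture
      pats3 <- all_histories(K, first = 3)
      for (r in seq_len(nrow(pats3))) {
        y <- pats3[r, ]
        expect_equal(exp(cjs_history_loglik(y, 3, phi, p)),
                     enum_history_prob(y, 3, phi, p), tolerance = 1e-12)
      }
    }
  }
})

test_that("closed-form and forward routes agree on simulated data", {
  ch <- simulate_dataset(scenario_spec("symmetric"), seed = 3)
  direct <- sum(vapply(seq_len(ch$n), function(i)
    cjs_history_loglik(ch$y[i, ], ch$first[i], 0.7, 0.4), numeric(1)))
  expect_equal(cjs_loglik(ch, 0.7, 0.4), direct, tolerance = 1e-8)
  # exchangeability: permutation of rows leaves the likelihood unchanged
  perm <- sample(ch$n)
  chp <- capture_history(ch$y[perm, ])
  expect_equal(cjs_loglik(chp, 0.7, 0.4), cjs_loglik(ch, 0.7, 0.4),
               tolerance = 1e-8)
})

test_that("all-detected history has likelihood (phi p)^(K-1)", {
  for (K in c(3, 8, 15)) {
    ch <- capture_history(matrix(1L, 1, K))
    expect_equal(cjs_loglik(ch, 0.7, 0.4), (K - 1) * log(0.7 * 0.4),
                 tolerance = 1e-10)
  }
})

test_that("single individual (1,1) reduces to log(phi p)", {
  ch <- capture_history(matrix(c(1L, 1L), 1))
  expect_equal(cjs_loglik(ch, 0.7, 0.4), log(0.28), tolerance = 1e-12)
})

test_that("time-varying likelihood reduces to constant when parameters repeat", {
  ch <- simulate_dataset(scenario_spec("symmetric", n_occasions = 6,
                                       n_new_per_occasion = 20), seed = 9)
  expect_equal(cjs_loglik(ch, rep(0.7, 5), rep(0.4, 5)),
               cjs_loglik(ch, 0.7, 0.4), tolerance = 1e-10)
  # and genuinely time-varying parameters match per-history recursion
  phi_t <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  p_t <- c(0.2, 0.3, 0.4, 0.5, 0.6)
  direct <- sum(vapply(seq_len(ch$n), function(i)
    cjs_history_loglik(ch$y[i, ], ch$first[i], phi_t, p_t), numeric(1)))
  expect_equal(cjs_loglik(ch, phi_t, p_t), direct, tolerance = 1e-8)
})

test_that("marginal likelihood with sigma = 0 equals the constant model", {
  ch <- simulate_dataset(scenario_spec("symmetric", n_occasions = 8,
                                       n_new_per_occasion = 15), seed = 2)
  expect_equal(cjs_loglik_re(ch, 0.7, qlogis(0.4), 0),
               cjs_loglik(ch, 0.7, 0.4), tolerance = 1e-10)
})

test_that("Gauss-Hermite marginal matches an adaptive-integration oracle", {
  sp <- scenario_spec("symmetric", n_occasions = 6, n_new_per_occasion = 5)
  ch <- simulate_dataset(sp, seed = 4)
  phi <- 0.7; mu <- qlogis(0.4); sigma <- 0.8
  oracle <- sum(vapply(seq_len(ch$n), function(i)
    log(integrate_history_marginal(ch$y[i, ], ch$first[i], phi, mu, sigma)),
    numeric(1)))
  expect_equal(cjs_loglik_re(ch, phi, mu, sigma, nodes = 40), oracle,
               tolerance = 1e-6)
})

test_that("quadrature stabilizes at the default node count on study-scale data", {
  ch <- simulate_dataset(scenario_spec("symmetric"), seed = 6)
  l25 <- cjs_loglik_re(ch, 0.7, qlogis(0.4), 0.62)          # default 25
  l40 <- cjs_loglik_re(ch, 0.7, qlogis(0.4), 0.62, nodes = 40)
  expect_lt(abs(l40 - l25), 1e-8)
})

test_that("implied_detection_sd bridges logit and probability scales", {
  expect_equal(implied_detection_sd(qlogis(0.4), 0), 0)
  # extreme heterogeneity piles mass at 0 and 1: SD approaches 0.5
  expect_gt(implied_detection_sd(0, 50), 0.49)
  # Monte-Carlo oracle
  set.seed(8)
  for (sigma in c(0.5, 1.5)) {
    draws <- plogis(qlogis(0.4) + rnorm(2e5, 0, sigma))
    expect_equal(implied_detection_sd(qlogis(0.4), sigma), sd(draws),
                 tolerance = 3 * sd(draws) / sqrt(2 * 2e5) + 1e-3)
    expect_lt(abs(implied_detection_mean(qlogis(0.4), sigma) - mean(draws)),
              3 * sd(draws) / sqrt(2e5))
  }
})

test_that("no spurious heterogeneity: sigma -> 0 preferred under homogeneous data", {
  # marginal log-likelihood at small sigma should not exceed sigma = 0
  # systematically when the generator is homogeneous
  diffs <- vapply(1:8, function(r) {
    ch <- simulate_dataset(homogeneous_spec(0.4, n_occasions = 10,
                                            n_new_per_occasion = 30),
                           seed = 100 + r)
    fit <- fit_cjs_mle(ch, "constant_p")
    at0 <- cjs_loglik_re(ch, fit$estimate["phi"],
                         qlogis(fit$estimate["p"]), 0)
    at05 <- cjs_loglik_re(ch, fit$estimate["phi"],
                          qlogis(fit$estimate["p"]), 0.5)
    at05 - at0
  }, numeric(1))
  expect_lt(mean(diffs), 0)
  expect_gt(mean(diffs < 0), 0.5)
})
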