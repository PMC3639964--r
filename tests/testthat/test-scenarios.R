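test_that("beta_from_moments matches the stated moments exactly", {
  cases <- list(c(0.4, 0.148), c(0.2, 0.163), c(0.8, 0.163), c(0.5, 0.2))
  for (cs in cases) {
    sh <- beta_from_moments(cs[1], cs[2])
    m <- sh[1] / sum(sh)
    v <- prod(sh) / (sum(sh)^2 * (sum(sh) + 1))
    expect_equal(unname(m), cs[1], tolerance = 1e-10)
    expect_equal(unname(sqrt(v)), cs[2], tolerance = 1e-10)
  }
  # frozen closed-form value for the symmetric scenario
  expect_equal(unname(beta_from_moments(0.4, 0.148)),
               c(3.982761, 5.974142), tolerance = 1e-6)
  # symmetry at mean 0.5
  sh <- beta_from_moments(0.5, 0.17)
  expect_equal(unname(sh[1]), unname(sh[2]))
})

test_that("beta_from_moments rejects moments outside the beta family", {
  expect_error(beta_from_moments(0.4, 0.49), "invalid beta moments")
  expect_error(beta_from_moments(0.4, 0), "invalid")
  expect_error(beta_from_moments(1.2, 0.1), "mean")
})

test_that("draw_individual_p honours each scenario's generating law", {
  two <- scenario_spec("two_group")
  d <- draw_individual_p(two, 500, seed = 1)
  expect_true(all(d$p %in% c(0.2, 0.8)))
  expect_true(all(d$group %in% 1:2))
  expect_identical(d$p, two$p_groups[d$group])
  # mixture weight 0.5: group-1 share within binomial error
  expect_lt(abs(mean(d$group == 1) - 0.5), 4 * sqrt(0.25 / 500))

  for (lab in c("symmetric", "right_skewed", "left_skewed")) {
    sp <- scenario_spec(lab)
    d <- draw_individual_p(sp, 1e5, seed = 2)
    expect_true(all(d$p > 0 & d$p < 1))
    mc_se <- sd(d$p) / sqrt(1e5)
    expect_lt(abs(mean(d$p) - sp$p_mean), 3 * mc_se)
  }

  d1 <- draw_individual_p(scenario_spec("symmetric"), 1, seed = 3)
  expect_equal(nrow(d1), 1)
  expect_true(d1$p > 0 && d1$p < 1)
})

test_that("two-group scenario has detection SD 0.3 at equal weights", {
  expect_equal(scenario_detection_sd(scenario_spec("two_group")), 0.3)
  expect_equal(scenario_detection_mean(scenario_spec("two_group")), 0.5)
  expect_equal(scenario_detection_sd(scenario_spec("symmetric")), 0.148)
})

test_that("simulated datasets satisfy the capture-history invariants", {
  for (lab in c("symmetric", "two_group")) {
    ch <- simulate_dataset(scenario_spec(lab), seed = 7)
    expect_s3_class(ch, "capture_history")
    expect_equal(dim(ch$y), c(750, 15))
    expect_true(all(ch$y %in% 0:1))
    expect_true(all(ch$y[cbind(seq_len(ch$n), ch$first)] == 1L))
    for (i in sample(ch$n, 50))
      if (ch$first[i] > 1)
        expect_true(all(ch$y[i, seq_len(ch$first[i] - 1)] == 0L))
    # release schedule: 50 new marks at every occasion incl. the last
    expect_equal(tabulate(ch$first, 15), rep(50, 15))
  }
})

test_that("degenerate survival/detection edges behave as expected", {
  # phi = 1, p = 1: every entry after first capture is a detection
  sp <- scenario_spec("two_group", phi = 1, p_groups = c(1, 1),
                      n_occasions = 6, n_new_per_occasion = 10)
  ch <- simulate_dataset(sp, seed = 1)
  for (i in seq_len(ch$n))
    expect_true(all(ch$y[i, ch$first[i]:ch$K] == 1L))

  # phi = 0: no individual is ever seen after its first capture
  sp0 <- scenario_spec("symmetric", phi = 0, n_occasions = 6,
                       n_new_per_occasion = 10)
  ch0 <- simulate_dataset(sp0, seed = 2)
  expect_true(all(rowSums(ch0$y) == 1L))
})

test_that("detection the occasion after release matches phi * E[p]", {
  sp <- scenario_spec("symmetric", n_occasions = 5, n_new_per_occasion = 900)
  ch <- simulate_dataset(sp, seed = 11)
  eligible <- ch$first < ch$K
  seen_next <- ch$y[cbind(which(eligible), ch$first[eligible] + 1L)]
  expected <- 0.7 * 0.4
  mc_se <- sqrt(expected * (1 - expected) / sum(eligible))
  expect_lt(abs(mean(seen_next) - expected), 3 * mc_se)
})

test_that("per-individual detection frequency converges to true_p (long study)", {
  sp <- scenario_spec("symmetric", phi = 0.98, n_occasions = 200,
                      n_new_per_occasion = 2)
  ch <- simulate_dataset(sp, seed = 5, keep_latent = TRUE)
  # occasions alive strictly after first capture
  alive_after <- ch$alive
  alive_after[cbind(seq_len(ch$n), ch$first)] <- 0L
  n_alive <- rowSums(alive_after)
  n_det <- rowSums(ch$y) - 1L
  keep <- n_alive >= 50
  expect_gt(sum(keep), 60)
  z <- (n_det[keep] - n_alive[keep] * ch$true_p[keep]) /
    sqrt(n_alive[keep] * ch$true_p[keep] * (1 - ch$true_p[keep]))
  # standardized binomial residuals: mean near 0, no individual wildly off
  expect_lt(abs(mean(z)), 3 / sqrt(sum(keep)) + 0.15)
  expect_lt(max(abs(z)), 5)
})

test_that("simulate_study is deterministic and maps seeds stably", {
  sp <- scenario_spec("symmetric", n_occasions = 6, n_new_per_occasion = 10)
  a <- simulate_study(sp, 3, seed = 42)
  b <- simulate_study(sp, 3, seed = 42)
  expect_identical(lapply(a, `[[`, "y"), lapply(b, `[[`, "y"))
  # replicate r reproduces simulate_dataset under the derived sub-seed
  sub <- attr(a, "sub_seeds")
  expect_identical(a[[2]]$y, simulate_dataset(sp, seed = sub[2])$y)
  # study dimensions at the canonical settings
  big <- simulate_study(scenario_spec("symmetric"), 2, seed = 1)
  expect_true(all(vapply(big, function(ch) all(dim(ch$y) == c(750, 15)),
                         logical(1))))
})

test_that("capture_history rejects invalid input", {
  expect_error(capture_history(matrix(c(1, 2, 0, 1), 2)), "0/1")
  expect_error(capture_history(rbind(c(0, 0, 0), c(1, 0, 1))),
               "detected at least once")
  expect_error(capture_history(rbind(c(1, 0), c(0, 1)),
                               first_capture = c(2, 2)), "inconsistent")
})
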