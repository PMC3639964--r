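# Independent oracles used across the suite. These deliberately avoid the
# package's computational routes: the likelihood oracle enumerates latent
# alive/dead paths directly; the quadrature oracle uses adaptive
# integration; the contingency oracle goes through chisq.test.

# Probability of a single history by enumeration over all monotone
# alive -> dead latent paths (death in interval d -> d+1, or survival to K).
enum_history_prob <- function(y, first, phi, p) {
  K <- length(y)
  if (first == K) return(1)
  total <- 0
  for (death_after in first:K) {    # last occasion alive
    prob <- if (death_after < K) {
      if (any(y[(death_after + 1):K] == 1)) next  # detection while dead
      pr <- 1
      if (death_after > first)
        for (t in (first + 1):death_after)
          pr <- pr * phi * (if (y[t] == 1) p else 1 - p)
      pr * (1 - phi)
    } else {
      pr <- 1
      for (t in (first + 1):K)
        pr <- pr * phi * (if (y[t] == 1) p else 1 - p)
      pr
    }
    total <- total + prob
  }
  total
}

# Marginal likelihood of one history over a logit-normal random effect,
# by adaptive quadrature (independent of Gauss-Hermite).
integrate_history_marginal <- function(y, first, phi, mu, sigma) {
  f <- Vectorize(function(eps)
    enum_history_prob(y, first, phi, stats::plogis(mu + eps)) *
      stats::dnorm(eps, 0, sigma))
  stats::integrate(f, -10 * sigma, 10 * sigma, rel.tol = 1e-10)$value
}

# All binary observation patterns of length K that start with a 1.
all_histories <- function(K, first = 1) {
  tail_len <- K - first
  grids <- rep(list(0:1), tail_len)
  tails <- as.matrix(expand.grid(grids))
  cbind(matrix(0, nrow(tails), first - 1),
        1, tails, deparse.level = 0)
}

# A tiny deterministic capture-history fixture.
toy_ch <- function() {
  capture_history(rbind(c(1, 0, 1),
                        c(1, 1, 0),
                        c(1, 1, 1),
                        c(0, 1, 1),
                        c(0, 0, 1)))
}

# Scenario with no heterogeneity (all individuals share p): a two-group
# spec with identical group probabilities.
homogeneous_spec <- function(p = 0.4, ...) {
  scenario_spec("two_group", p_groups = c(p, p), ...)
}
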