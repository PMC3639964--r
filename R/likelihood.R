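## CJS likelihood machinery.
##
## Two computational routes are provided and cross-checked in the test suite:
##  - a closed-form route for time-constant survival and per-individual
##    constant detection: the individual likelihood factorizes as
##    phi^(L-f) * p^d * (1-p)^(L-f-d) * chi_L, where f is first capture,
##    L last detection, d the number of re-detections, and chi_t the
##    probability of never being seen after t
##    (chi_K = 1, chi_t = (1-phi) + phi (1-p) chi_{t+1});
##  - a general alive/dead forward recursion (hidden two-state process,
##    dead absorbing with detection probability 0) that also covers
##    time-varying parameters and boundary parameter values.

# Gauss-Hermite rule transformed for E[f(eps)], eps ~ N(0,1):
# nodes sqrt(2)*x, weights w/sqrt(pi) (weights sum to 1).
.gh_rule <- function(nodes) {
  stopifnot(nodes >= 1)
  gh <- pracma::gaussHermite(nodes)
  list(x = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

# Sufficient statistics of each history for the closed-form route.
.cjs_prep <- function(ch) {
  stopifnot(inherits(ch, "capture_history"))
  y <- ch$y
  last <- if (ch$n > 0) ch$K + 1L - max.col(y[, ch$K:1, drop = FALSE] == 1L,
                                            ties.method = "first")
          else integer(0)
  list(f = ch$first, L = last, d = as.integer(rowSums(y) - 1L),
       n = ch$n, K = ch$K, y = y)
}

# chi recursion, vectorized over columns of p (one column per quadrature
# node); p and the returned chi are indexed by occasion 1..K (chi[t, q]).
.chi_table <- function(K, phi, p) {
  p <- matrix(p, nrow = K, ncol = length(p) / K)
  chi <- matrix(1, K, ncol(p))
  if (K >= 2) for (t in (K - 1L):1L)
    chi[t, ] <- (1 - phi) + phi * (1 - p[t + 1L, ]) * chi[t + 1L, ]
  chi
}

# Closed-form per-individual log-likelihood matrix (n x Q) for constant phi
# and occasion-constant detection; pq is a Q-vector of detection
# probabilities (one per quadrature node), all in (0,1); phi in (0,1).
.ll_matrix_closed <- function(prep, phi, pq) {
  # extreme quadrature nodes can saturate plogis to exactly 0/1; clamp so
  # that impossible-but-zero-count terms stay 0 * finite, not 0 * Inf
  pq <- pmin(pmax(pq, 1e-15), 1 - 1e-15)
  Q <- length(pq)
  chi <- .chi_table(prep$K, phi, matrix(pq, prep$K, Q, byrow = TRUE))
  nf <- prep$L - prep$f
  out <- nf * log(phi) +
    outer(prep$d, log(pq)) + outer(nf - prep$d, log1p(-pq)) +
    log(chi)[prep$L, , drop = FALSE]
  out
}

# General forward recursion over the alive/dead hidden process.
# phi_t: length K-1 (interval t -> t+1); P: K x Q matrix of detection
# probabilities by occasion (row 1 unused). Returns n x Q log-likelihoods.
.ll_matrix_forward <- function(Y, first, phi_t, P) {
  n <- nrow(Y); K <- ncol(Y); Q <- ncol(P)
  A <- matrix(1, n, Q)   # P(alive at t, obs so far)
  D <- matrix(0, n, Q)   # P(dead at t, obs so far)
  for (t in 2:K) {
    act <- which(first < t)
    if (!length(act)) next
    yt <- Y[act, t]
    Aa <- A[act, , drop = FALSE]
    Da <- D[act, , drop = FALSE]
    obs <- outer(yt, P[t, ]) + outer(1 - yt, 1 - P[t, ])
    A[act, ] <- Aa * phi_t[t - 1L] * obs
    D[act, ] <- (Da + Aa * (1 - phi_t[t - 1L])) * (1 - yt)
  }
  log(A + D)
}

.rowlogsumexp_w <- function(ll, w) {
  mx <- ll[cbind(seq_len(nrow(ll)), max.col(ll, ties.method = "first"))]
  mx[!is.finite(mx)] <- 0
  mx + log(exp(ll - mx) %*% w)
}

.expand_phi <- function(phi, K) {
  if (length(phi) == 1L) rep(phi, K - 1L)
  else if (length(phi) == K - 1L) phi
  else stop("phi must be a scalar or have length n_occasions - 1")
}

.expand_p <- function(p, K) {
  # detection applies to occasions 2..K; accepted as scalar or length K-1
  if (length(p) == 1L) rep(p, K)
  else if (length(p) == K - 1L) c(NA_real_, p)
  else stop("p must be a scalar or have length n_occasions - 1")
}

#' Log-likelihood of a single capture history
#'
#' Exact log-probability of the observations after first capture under the
#' two-state (alive/dead) hidden process of the CJS model, computed by
#' forward recursion: the alive state survives each interval with
#' probability `phi` and is detected with probability `p`; the dead state is
#' absorbing and never detected. The state at first capture is known
#' (alive with certainty).
#'
#' @param y binary vector, one entry per occasion.
#' @param first first-capture occasion (`y[first]` must be 1).
#' @param phi survival probability, scalar or per-interval vector
#'   (length `length(y) - 1`).
#' @param p detection probability, scalar or per-occasion vector for
#'   occasions `2..K` (length `length(y) - 1`).
#' @return log-probability (0 for an individual first captured at the
#'   final occasion).
#' @export
cjs_history_loglik <- function(y, first, phi, p) {
  y <- as.integer(y); K <- length(y)
  if (K < 2) stop("history must cover at least 2 occasions")
  if (first < 1 || first > K) stop("first capture occasion out of range")
  if (y[first] != 1L) stop("individual must be detected at its first capture")
  if (first > 1L && any(y[seq_len(first - 1L)] != 0L))
    stop("detections before first capture are invalid")
  phi_t <- .expand_phi(phi, K)
  P <- matrix(.expand_p(p, K), K, 1)
  drop(.ll_matrix_forward(matrix(y, 1), first, phi_t, P))
}

#' CJS log-likelihood with homogeneous (or time-varying) detection
#'
#' Sums the per-history log-likelihoods over all individuals under shared
#' parameters. Scalars give the constant model `{phi, p}`; vectors give the
#' fixed-time-effect variant (per-interval survival, per-occasion detection).
#'
#' @param ch a [capture_history()].
#' @param phi survival, scalar or length `K - 1`.
#' @param p detection, scalar or length `K - 1` (occasions `2..K`).
#' @return total log-likelihood.
#' @export
cjs_loglik <- function(ch, phi, p) {
  stopifnot(inherits(ch, "capture_history"))
  if (ch$n == 0L) return(0)
  K <- ch$K
  scalar <- length(phi) == 1L && length(p) == 1L
  if (scalar && phi > 0 && phi < 1 && p > 0 && p < 1) {
    prep <- .cjs_prep(ch)
    return(sum(.ll_matrix_closed(prep, phi, p)))
  }
  phi_t <- .expand_phi(phi, K)
  P <- matrix(.expand_p(p, K), K, 1)
  sum(.ll_matrix_forward(ch$y, ch$first, phi_t, P))
}

#' Marginal CJS log-likelihood with logit-normal individual detection
#'
#' Detection heterogeneity is modelled as `logit(p_i) = mu + eps_i` with
#' `eps_i ~ Normal(0, sigma^2)`. Each individual's likelihood is integrated
#' over its random effect by Gauss-Hermite quadrature and the log-likelihoods
#' are summed. With `sigma = 0` this equals [cjs_loglik()] at
#' `p = plogis(mu)` exactly.
#'
#' @param ch a [capture_history()].
#' @param phi survival, scalar or length `K - 1` (fixed time effects).
#' @param mu global mean detection on the logit scale, scalar or length
#'   `K - 1` (occasions `2..K`).
#' @param sigma standard deviation of the individual deviations on the
#'   logit scale (`>= 0`).
#' @param nodes number of Gauss-Hermite quadrature nodes (default 25).
#' @return total log-likelihood.
#' @export
cjs_loglik_re <- function(ch, phi, mu, sigma, nodes = 25) {
  stopifnot(inherits(ch, "capture_history"), sigma >= 0, nodes >= 1)
  if (ch$n == 0L) return(0)
  if (sigma == 0) {
    p <- stats::plogis(mu)
    return(cjs_loglik(ch, phi, if (length(p) == 1L) p else p))
  }
  K <- ch$K
  gh <- .gh_rule(nodes)
  scalar <- length(phi) == 1L && length(mu) == 1L
  if (scalar && phi > 0 && phi < 1) {
    prep <- .cjs_prep(ch)
    pq <- stats::plogis(mu + sigma * gh$x)
    ll <- .ll_matrix_closed(prep, phi, pq)
  } else {
    phi_t <- .expand_phi(phi, K)
    mu_occ <- .expand_p(mu, K)   # same layout: occasions 2..K
    P <- stats::plogis(outer(mu_occ, sigma * gh$x, "+"))
    ll <- .ll_matrix_forward(ch$y, ch$first, phi_t, P)
  }
  out <- .rowlogsumexp_w(ll, gh$w)
  if (any(!is.finite(out) & ch$first < K))
    stop("non-finite marginal likelihood for individual(s) ",
         paste(utils::head(which(!is.finite(out)), 5), collapse = ", "))
  sum(out)
}

#' Probability-scale SD of detection implied by logit-normal heterogeneity
#'
#' Standard deviation of `plogis(mu + eps)` with `eps ~ Normal(0, sigma^2)`,
#' computed by Gauss-Hermite quadrature. Used to compare a fitted logit-scale
#' heterogeneity SD with a generating probability-scale SD.
#'
#' @param mu mean detection on the logit scale.
#' @param sigma logit-scale SD (`>= 0`).
#' @param nodes quadrature size (default 60).
#' @return probability-scale SD (0 when `sigma = 0`).
#' @export
implied_detection_sd <- function(mu, sigma, nodes = 60) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(0)
  gh <- .gh_rule(nodes)
  g <- stats::plogis(mu + sigma * gh$x)
  m1 <- sum(gh$w * g)
  m2 <- sum(gh$w * g^2)
  sqrt(max(m2 - m1^2, 0))
}

#' Mean detection probability implied by logit-normal heterogeneity
#' @inheritParams implied_detection_sd
#' @return probability-scale mean of `plogis(mu + eps)`.
#' @export
implied_detection_mean <- function(mu, sigma, nodes = 60) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(stats::plogis(mu))
  gh <- .gh_rule(nodes)
  sum(gh$w * stats::plogis(mu + sigma * gh$x))
}
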