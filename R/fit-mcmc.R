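## Bayesian fitting by adaptive componentwise random-walk Metropolis on the
## marginalized CJS likelihood. Priors follow the study protocol: U(0,1) on
## survival and on the mean detection probability, U(0,10) on the logit-scale
## heterogeneity SD. Proposal scales adapt during burn-in only, so the kept
## samples target the exact posterior.

#' Prior specification for the Bayesian CJS fits
#'
#' Uniform, non-informative priors: `phi ~ U(0,1)`, mean detection
#' probability `~ U(0,1)` (the logit-scale mean `mu` is the logit of this
#' uniform variate), and heterogeneity SD `sigma ~ U(0, sigma_max)` with
#' `sigma_max = 10`.
#'
#' @return List with elements `phi`, `p_mean`, `sigma`, each giving
#'   `c(lower, upper)` of the uniform support, plus a `density(par, value)`
#'   function.
#' @export
make_priors <- function() {
  sup <- list(phi = c(0, 1), p_mean = c(0, 1), sigma = c(0, 10))
  dens <- function(par, value) {
    b <- sup[[par]]
    ifelse(value >= b[1] & value <= b[2], 1 / diff(b), 0)
  }
  c(sup, list(density = dens))
}

# log-posterior closure; theta on the natural scale
.make_lpost <- function(ch, model, nodes) {
  prep <- .cjs_prep(ch)
  priors <- make_priors()
  if (model == "constant_p") {
    lo <- c(0, 0); hi <- c(1, 1)
    ll <- function(theta) sum(.ll_matrix_closed(prep, theta[1], theta[2]))
  } else {
    lo <- c(0, 0, priors$sigma[1]); hi <- c(1, 1, priors$sigma[2])
    gh <- .gh_rule(nodes)
    ll <- function(theta) {
      if (theta[3] == 0)
        return(sum(.ll_matrix_closed(prep, theta[1], theta[2])))
      pq <- stats::plogis(stats::qlogis(theta[2]) + theta[3] * gh$x)
      sum(.rowlogsumexp_w(.ll_matrix_closed(prep, theta[1], pq), gh$w))
    }
  }
  function(theta) {
    if (any(theta <= lo) || any(theta >= hi)) return(-Inf)
    ll(theta)   # flat priors: constant inside the support
  }
}

.mcmc_param_names <- function(model)
  if (model == "constant_p") c("phi", "p") else c("phi", "p_mean", "sigma")

# one chain of adaptive componentwise random-walk Metropolis
.run_chain <- function(lpost, init, iter, burnin, thin, scales) {
  d <- length(init)
  theta <- init
  lp <- lpost(theta)
  n_keep <- floor((iter - burnin) / thin)
  kept <- matrix(NA_real_, n_keep, d)
  acc <- numeric(d); prop <- numeric(d)
  k <- 0L
  for (i in seq_len(iter)) {
    for (j in seq_len(d)) {
      cand <- theta
      cand[j] <- theta[j] + stats::rnorm(1, 0, scales[j])
      lp_cand <- lpost(cand)
      accept <- is.finite(lp_cand) && log(stats::runif(1)) < lp_cand - lp
      if (accept) { theta <- cand; lp <- lp_cand }
      if (i <= burnin) {           # diminishing adaptation, burn-in only
        gain <- min(0.1, 3 / sqrt(i))
        scales[j] <- scales[j] * exp(gain * ((accept) - 0.44))
      } else {
        prop[j] <- prop[j] + 1; acc[j] <- acc[j] + accept
      }
    }
    if (i > burnin && (i - burnin) %% thin == 0L && k < n_keep) {
      k <- k + 1L
      kept[k, ] <- theta
    }
  }
  list(samples = kept, scales = scales,
       acc_rate = ifelse(prop > 0, acc / prop, NA_real_))
}

#' Bayesian MCMC fit of a CJS model
#'
#' Samples the posterior of the constant-detection model (`phi`, `p`) or the
#' logit-normal random-effects model (`phi`, `p_mean`, `sigma`) under the
#' priors of [make_priors()], using componentwise random-walk Metropolis on
#' the Gauss-Hermite-marginalized likelihood. Proposal standard deviations
#' adapt during burn-in only. Initial values are drawn from the priors.
#'
#' The default protocol is a single chain of 30000 iterations, burn-in
#' 20000, keeping every 10th draw (1000 kept samples). With `chains >= 2`
#' the Brooks-Gelman-Rubin statistic is reported per parameter.
#'
#' @param ch a [capture_history()].
#' @param model `"constant_p"` or `"re_p"`.
#' @param chains number of chains.
#' @param iter,burnin,thin chain protocol (`iter > burnin`, `thin >= 1`).
#' @param nodes Gauss-Hermite quadrature size for `"re_p"`.
#' @param seed integer seed (one sub-seed per chain is derived from it).
#' @param init optional list (one numeric vector per chain) of initial
#'   values; drawn from the priors when `NULL`.
#' @return Object of class `cjs_fit` with `method = "mcmc"`: `samples`
#'   (list of kept-sample matrices, one per chain), a `summary` data frame
#'   (posterior mean, SD, 2.5/50/97.5 percentiles, rhat), `estimate`
#'   (posterior means), `n_kept` per chain, and the protocol settings.
#' @export
fit_cjs_mcmc <- function(ch, model = c("constant_p", "re_p"), chains = 1,
                         iter = 30000, burnin = 20000, thin = 10,
                         nodes = 25, seed = NULL, init = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(ch, "capture_history"))
  if (iter <= burnin) stop("iter must exceed burnin")
  if (thin < 1) stop("thin must be >= 1")
  n_keep <- floor((iter - burnin) / thin)
  if (n_keep < 1) stop("configuration yields zero kept samples")
  nm <- .mcmc_param_names(model)
  d <- length(nm)
  lpost <- .make_lpost(ch, model, nodes)

  if (!is.null(seed)) set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max, chains)
  draw_init <- function() {
    for (. in 1:50) {
      th <- stats::runif(d, c(0.01, 0.01, 0)[seq_len(d)],
                         c(0.99, 0.99, 10)[seq_len(d)])
      if (is.finite(lpost(th))) return(th)
    }
    stop("could not find initial values with finite posterior density")
  }
  base_scales <- c(0.05, 0.05, 0.2)[seq_len(d)]

  runs <- lapply(seq_len(chains), function(c_i) {
    set.seed(chain_seeds[c_i])
    th0 <- if (!is.null(init)) init[[c_i]] else draw_init()
    if (!is.finite(lpost(th0)))
      stop("initial values have non-finite posterior density")
    .run_chain(lpost, th0, iter, burnin, thin, base_scales)
  })
  samples <- lapply(runs, function(r) {
    colnames(r$samples) <- nm
    r$samples
  })
  all_s <- do.call(rbind, samples)
  qs <- apply(all_s, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  rhat <- if (chains >= 2) bgr_diagnostic(samples) else rep(NA_real_, d)
  summ <- data.frame(parameter = nm, mean = colMeans(all_s),
                     sd = apply(all_s, 2, stats::sd),
                     q2.5 = qs[1, ], q50 = qs[2, ], q97.5 = qs[3, ],
                     rhat = rhat, row.names = NULL)
  fit <- list(method = "mcmc", model = model, samples = samples,
              summary = summ, estimate = stats::setNames(colMeans(all_s), nm),
              n_kept = n_keep, chains = chains, iter = iter, burnin = burnin,
              thin = thin, seed = seed, nodes = if (model == "re_p") nodes,
              acc_rate = rowMeans(sapply(runs, `[[`, "acc_rate")),
              mu = if (model == "re_p")
                unname(stats::qlogis(mean(all_s[, "p_mean"]))),
              n = ch$n, K = ch$K)
  class(fit) <- "cjs_fit"
  fit
}

#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' Computes, per parameter, `sqrt(Vhat / W)` with `W` the mean within-chain
#' variance, `B/n` the variance of the chain means, and
#' `Vhat = (n-1)/n W + (1 + 1/m) B/n` for `m` chains of length `n`.
#' Values near 1 indicate convergence; the study protocol requires < 1.01.
#'
#' @param chains list of numeric matrices (kept samples; equal dimensions,
#'   parameters in columns) or of numeric vectors for a single parameter.
#' @return Named numeric vector of statistics, one per parameter.
#' @export
bgr_diagnostic <- function(chains) {
  if (is.matrix(chains)) chains <- list(chains)
  if (length(chains) < 2)
    stop("Brooks-Gelman-Rubin diagnostic requires at least 2 chains")
  chains <- lapply(chains, function(x) if (is.matrix(x)) x else cbind(x))
  dims <- vapply(chains, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all chains must have identical dimensions")
  n <- dims[1, 1]; m <- length(chains)
  vapply(seq_len(dims[2, 1]), function(j) {
    x <- sapply(chains, function(ch) ch[, j])   # n x m
    W <- mean(apply(x, 2, stats::var))
    B_over_n <- stats::var(colMeans(x))
    if (W == 0) return(1)
    vhat <- (n - 1) / n * W + (1 + 1 / m) * B_over_n
    sqrt(vhat / W)
  }, numeric(1)) -> r
  names(r) <- colnames(chains[[1]])
  r
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat(sprintf("CJS fit (%s, model '%s'), %d individuals x %d occasions\n",
              x$method, x$model, x$n, x$K))
  if (x$method == "mcmc") {
    cat(sprintf("  %d chain(s) x %d iter, burn-in %d, thin %d -> %d kept/chain\n",
                x$chains, x$iter, x$burnin, x$thin, x$n_kept))
    print(format(x$summary, digits = 4), row.names = FALSE)
  } else {
    est <- format(x$estimate, digits = 4)
    se <- format(x$se, digits = 3)
    for (i in seq_along(est))
      cat(sprintf("  %-8s %s (se %s)\n", names(x$estimate)[i], est[i], se[i]))
    cat(sprintf("  logLik %.3f%s\n", x$loglik,
                if (isTRUE(x$boundary)) "  [sigma at boundary]" else ""))
  }
  invisible(x)
}

#' Posterior/ML summary table of a CJS fit
#' @param object a `cjs_fit`.
#' @param ... unused.
#' @return data.frame with columns parameter, mean, sd, q2.5, q50, q97.5,
#'   rhat (quantiles and rhat are `NA` for ML fits).
#' @export
summary.cjs_fit <- function(object, ...) {
  if (object$method == "mcmc") return(object$summary)
  data.frame(parameter = names(object$estimate),
             mean = unname(object$estimate), sd = unname(object$se),
             q2.5 = NA_real_, q50 = NA_real_, q97.5 = NA_real_,
             rhat = NA_real_, row.names = NULL)
}

#' @export
coef.cjs_fit <- function(object, ...) object$estimate
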