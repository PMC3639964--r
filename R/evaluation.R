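## Replicate-study driver: simulate datasets under each heterogeneity
## scenario, fit the constant-detection and random-effects models to each,
## and summarize relative bias and precision of the survival estimate and
## the bias of the estimated probability-scale detection SD.

#' Relative bias of a set of estimates
#'
#' Mean over replicates of `(estimate - truth) / truth`.
#'
#' @param estimates numeric vector of per-replicate point estimates.
#' @param truth generating value (nonzero).
#' @return dimensionless relative bias.
#' @export
relative_bias <- function(estimates, truth) {
  if (!length(estimates)) stop("estimates must be nonempty")
  if (truth == 0) stop("truth must be nonzero")
  mean((estimates - truth) / truth)
}

#' MCMC protocol settings
#'
#' Defaults follow the study protocol: a single chain of 30000 iterations,
#' burn-in 20000, thinning 10 (1000 kept samples).
#'
#' @param chains,iter,burnin,thin see [fit_cjs_mcmc()].
#' @return list of protocol settings.
#' @export
mcmc_protocol <- function(chains = 1, iter = 30000, burnin = 20000,
                          thin = 10) {
  stopifnot(iter > burnin, thin >= 1, chains >= 1)
  list(chains = chains, iter = iter, burnin = burnin, thin = thin)
}

# fit one dataset with one model under the chosen engine, returning the
# summaries the study needs (or NULL on failure)
.fit_one <- function(ch, model, engine, protocol, nodes, seed) {
  fit <- if (engine == "mle") fit_cjs_mle(ch, model, nodes = nodes)
         else fit_cjs_mcmc(ch, model, chains = protocol$chains,
                           iter = protocol$iter, burnin = protocol$burnin,
                           thin = protocol$thin, nodes = nodes, seed = seed)
  phi_hat <- unname(fit$estimate["phi"])
  phi_sd <- if (engine == "mle") unname(fit$se["phi"])
            else fit$summary$sd[fit$summary$parameter == "phi"]
  out <- list(phi_hat = phi_hat, phi_sd = phi_sd,
              phi_lo = NA_real_, phi_hi = NA_real_,
              sigma_hat = NA_real_, p_sd_hat = NA_real_,
              boundary = isTRUE(fit$boundary))
  if (engine == "mcmc") {
    row <- fit$summary[fit$summary$parameter == "phi", ]
    out$phi_lo <- row$q2.5; out$phi_hi <- row$q97.5
  }
  if (model == "re_p") {
    out$sigma_hat <- unname(fit$estimate["sigma"])
    out$p_sd_hat <- implied_detection_sd(fit$mu, out$sigma_hat)
  }
  out
}

#' Run a replicate bias/precision study
#'
#' For each scenario: simulates `n_replicates` datasets
#' ([simulate_study()]), fits each requested model to each dataset with the
#' chosen engine (fast ML on the marginalized likelihood, or MCMC under
#' `protocol`), and records the survival point estimate and its SD, plus —
#' for the random-effects model — the fitted heterogeneity converted to a
#' probability-scale detection SD via [implied_detection_sd()]. The point
#' estimate is the posterior mean (MCMC) or the MLE.
#'
#' Per-replicate fit failures are caught, counted and reported; they are
#' never silently dropped.
#'
#' @param scenarios a [scenario_spec()] or (named) list of them.
#' @param models character subset of `c("constant_p", "re_p")`.
#' @param n_replicates replicate datasets per scenario.
#' @param engine `"mle"` or `"mcmc"`.
#' @param protocol [mcmc_protocol()] settings (MCMC engine only).
#' @param nodes Gauss-Hermite quadrature size.
#' @param seed master seed; per-scenario and per-fit sub-seeds are derived
#'   deterministically from it.
#' @return Object of class `cmr_study`: `estimates` (per-replicate data
#'   frame) and the configuration. Summarize with [bias_report()].
#' @export
run_replicate_study <- function(scenarios, models = c("constant_p", "re_p"),
                                n_replicates = 100,
                                engine = c("mle", "mcmc"),
                                protocol = mcmc_protocol(), nodes = 25,
                                seed = 1) {
  engine <- match.arg(engine)
  stopifnot(all(models %in% c("constant_p", "re_p")), n_replicates >= 1)
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, `[[`, character(1), "label")

  set.seed(seed)
  scen_seeds <- sample.int(.Machine$integer.max, length(scenarios))
  rows <- list()
  for (s in seq_along(scenarios)) {
    spec <- scenarios[[s]]
    datasets <- simulate_study(spec, n_replicates, seed = scen_seeds[s])
    set.seed(scen_seeds[s] %% 1000003L + 7L)
    fit_seeds <- sample.int(.Machine$integer.max,
                            n_replicates * length(models))
    k <- 0
    for (r in seq_len(n_replicates)) {
      for (mod in models) {
        k <- k + 1
        res <- tryCatch(.fit_one(datasets[[r]], mod, engine, protocol,
                                 nodes, fit_seeds[k]),
                        error = function(e) e)
        failed <- inherits(res, "error")
        rows[[length(rows) + 1]] <- data.frame(
          scenario = names(scenarios)[s], model = mod, replicate = r,
          failed = failed,
          error = if (failed) conditionMessage(res) else NA_character_,
          phi_hat = if (failed) NA_real_ else res$phi_hat,
          phi_sd = if (failed) NA_real_ else res$phi_sd,
          phi_lo = if (failed) NA_real_ else res$phi_lo,
          phi_hi = if (failed) NA_real_ else res$phi_hi,
          sigma_hat = if (failed) NA_real_ else res$sigma_hat,
          p_sd_hat = if (failed) NA_real_ else res$p_sd_hat,
          boundary = if (failed) NA else res$boundary)
      }
    }
  }
  structure(list(estimates = do.call(rbind, rows),
                 scenarios = scenarios, models = models,
                 n_replicates = n_replicates, engine = engine,
                 protocol = if (engine == "mcmc") protocol, nodes = nodes,
                 seed = seed),
            class = "cmr_study")
}

#' @export
print.cmr_study <- function(x, ...) {
  cat(sprintf(
    "CMR replicate study: %d scenario(s) x %d replicate(s), engine %s\n",
    length(x$scenarios), x$n_replicates, x$engine))
  print(bias_report(x), digits = 3)
  invisible(x)
}

#' Bias and precision summary of a replicate study
#'
#' Per (scenario, model): relative bias of the survival estimate against
#' the generating survival, its Monte-Carlo standard error, the mean SD of
#' the survival estimate (posterior SD or asymptotic SE), and — for the
#' random-effects model — the relative bias of the estimated
#' probability-scale detection SD against the scenario's generating SD
#' ([scenario_detection_sd()]).
#'
#' @param study a `cmr_study` from [run_replicate_study()].
#' @return data.frame of class `bias_report`.
#' @export
bias_report <- function(study) {
  stopifnot(inherits(study, "cmr_study"))
  est <- study$estimates
  out <- list()
  for (s in names(study$scenarios)) {
    spec <- study$scenarios[[s]]
    truth_sd <- scenario_detection_sd(spec)
    for (mod in study$models) {
      e <- est[est$scenario == s & est$model == mod, ]
      ok <- e[!e$failed, ]
      n_ok <- nrow(ok)
      rb <- (ok$phi_hat - spec$phi) / spec$phi
      sd_rb <- if (mod == "re_p") (ok$p_sd_hat - truth_sd) / truth_sd
      out[[length(out) + 1]] <- data.frame(
        scenario = s, model = mod,
        n_replicates = nrow(e), n_failed = sum(e$failed),
        phi_true = spec$phi,
        phi_bias = mean(rb),
        phi_bias_mcse = stats::sd(rb) / sqrt(n_ok),
        mean_phi_sd = mean(ok$phi_sd, na.rm = TRUE),
        p_sd_true = if (mod == "re_p") truth_sd else NA_real_,
        p_sd_bias = if (mod == "re_p") mean(sd_rb) else NA_real_,
        p_sd_bias_mcse = if (mod == "re_p") stats::sd(sd_rb) / sqrt(n_ok)
                         else NA_real_)
    }
  }
  out <- do.call(rbind, out)
  class(out) <- c("bias_report", "data.frame")
  out
}

#' Paired precision comparison between models
#'
#' Compares, per scenario, the mean SD of the survival estimate under the
#' heterogeneity model against the constant-detection model on the same
#' replicates (paired differences with their Monte-Carlo standard error).
#' A positive difference means the heterogeneity model is less precise.
#'
#' @param study a `cmr_study` fitted with both models.
#' @return data.frame with one row per scenario: mean SD under each model,
#'   mean paired difference (`re_p` minus `constant_p`) and its MC SE.
#' @export
precision_comparison <- function(study) {
  stopifnot(inherits(study, "cmr_study"))
  if (!all(c("constant_p", "re_p") %in% study$models))
    stop("precision comparison needs both models on the same replicates")
  est <- study$estimates[!study$estimates$failed, ]
  out <- lapply(names(study$scenarios), function(s) {
    a <- est[est$scenario == s & est$model == "re_p", ]
    b <- est[est$scenario == s & est$model == "constant_p", ]
    common <- intersect(a$replicate, b$replicate)
    if (!length(common)) stop("no matched replicates for scenario ", s)
    d <- a$phi_sd[match(common, a$replicate)] -
      b$phi_sd[match(common, b$replicate)]
    data.frame(scenario = s, n = length(common),
               mean_sd_re = mean(a$phi_sd[match(common, a$replicate)]),
               mean_sd_constant = mean(b$phi_sd[match(common, b$replicate)]),
               sd_difference = mean(d),
               sd_difference_mcse = stats::sd(d) / sqrt(length(d)))
  })
  do.call(rbind, out)
}

#' Plot a bias report
#'
#' Two-panel summary in the style of a simulation-study figure: relative
#' bias of the survival estimate, and its mean SD, per scenario and model.
#' Requires ggplot2.
#'
#' @param report a [bias_report()].
#' @return a ggplot object (patchwork-free two-facet plot).
#' @export
plot_bias_report <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_bias_report requires the ggplot2 package")
  df <- rbind(
    data.frame(scenario = report$scenario, model = report$model,
               panel = "relative bias of survival estimate",
               value = report$phi_bias),
    data.frame(scenario = report$scenario, model = report$model,
               panel = "SD of survival estimate",
               value = report$mean_phi_sd))
  ggplot2::ggplot(df, ggplot2::aes(x = scenario, y = value, shape = model)) +
    ggplot2::geom_point(size = 3,
                        position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::scale_shape_manual(values = c(constant_p = 16, re_p = 1)) +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::geom_hline(data = data.frame(
      panel = "relative bias of survival estimate", y = 0),
      ggplot2::aes(yintercept = y), linetype = 2) +
    ggplot2::labs(x = "scenario", y = NULL) +
    ggplot2::theme_bw()
}
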