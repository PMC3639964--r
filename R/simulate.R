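#' Simulate one capture-mark-recapture dataset
#'
#' Simulates a CJS-structured dataset under a heterogeneity scenario:
#' `n_new_per_occasion` individuals are first marked at each occasion
#' 1..K; conditional on first capture, the latent alive state evolves as
#' Bernoulli(phi) per interval (death is absorbing) and detection while alive
#' is Bernoulli(p_i) per occasion, with p_i the individual's own detection
#' probability drawn once from the scenario distribution. Dead individuals
#' are never detected. No pre-marking process is modelled, matching the CJS
#' conditioning on first capture. The final cohort (marked at occasion K)
#' carries no recapture information but is retained.
#'
#' @param spec a [scenario_spec()].
#' @param seed optional integer seed.
#' @param keep_latent keep the latent alive matrix (debug mode)?
#' @return A [capture_history()] with `true_p` (and `true_group`) recorded.
#' @export
simulate_dataset <- function(spec, seed = NULL, keep_latent = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  K <- spec$n_occasions
  m <- spec$n_new_per_occasion
  n <- K * m
  first <- rep(seq_len(K), each = m)
  ind <- draw_individual_p(spec, n)

  z <- matrix(0L, n, K)   # latent alive
  y <- matrix(0L, n, K)   # detections
  z[cbind(seq_len(n), first)] <- 1L
  y[cbind(seq_len(n), first)] <- 1L
  for (t in seq_len(K - 1L) + 1L) {
    prev <- z[, t - 1L] == 1L & first < t
    z[prev, t] <- stats::rbinom(sum(prev), 1L, spec$phi)
    det <- z[, t] == 1L & first < t
    y[det, t] <- stats::rbinom(sum(det), 1L, ind$p[det])
  }
  capture_history(y, true_p = ind$p,
                  true_group = if (spec$label == "two_group") ind$group,
                  alive = if (keep_latent) z,
                  scenario = spec$label)
}

#' Simulate a replicate study
#'
#' Generates `n_replicates` independent datasets from one scenario. A single
#' study-level seed deterministically spawns one sub-seed per replicate:
#' `set.seed(seed)` followed by `sample.int(.Machine$integer.max,
#' n_replicates)`; replicate r is then `simulate_dataset(spec, sub_seed[r])`.
#' The mapping is stable across machines (R's default Mersenne-Twister).
#'
#' @param spec a [scenario_spec()].
#' @param n_replicates number of replicate datasets.
#' @param seed study-level integer seed.
#' @return List of [capture_history()] objects; the sub-seeds are attached
#'   as attribute `"sub_seeds"`.
#' @export
simulate_study <- function(spec, n_replicates, seed) {
  stopifnot(n_replicates >= 1)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max, n_replicates)
  out <- lapply(sub, function(s) simulate_dataset(spec, seed = s))
  attr(out, "sub_seeds") <- sub
  out
}
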