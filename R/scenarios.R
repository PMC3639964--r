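#' Heterogeneity scenario specifications
#'
#' A `scenario_spec` describes one generating regime for individual detection
#' probabilities in a capture-mark-recapture study: either a beta distribution
#' given by its probability-scale mean and standard deviation, or a two-group
#' mixture with fixed group detection probabilities. The study dimensions
#' (number of occasions, newly marked individuals per occasion) and the true
#' constant survival probability are part of the specification.
#'
#' The four canonical scenarios (see [cmr_scenarios()]) are:
#' \describe{
#'   \item{symmetric}{beta, mean 0.4, SD 0.148 — heterogeneity symmetric
#'     around the mean detection probability.}
#'   \item{right_skewed}{beta, mean 0.2, SD 0.163 — most individuals have low
#'     detection probability, a few are caught repeatedly.}
#'   \item{left_skewed}{beta, mean 0.8, SD 0.163 — most individuals have high
#'     detection probability.}
#'   \item{two_group}{a mixture of two latent groups with detection
#'     probabilities 0.2 and 0.8 that cannot be told apart in the field.}
#' }
#'
#' @param label scenario label, one of `"symmetric"`, `"right_skewed"`,
#'   `"left_skewed"`, `"two_group"`.
#' @param n_occasions number of sampling occasions (default 15).
#' @param n_new_per_occasion newly marked individuals released at each
#'   occasion (default 50).
#' @param phi true apparent survival probability per interval (default 0.7).
#' @param p_mean,p_sd probability-scale mean and SD of the beta scenarios;
#'   defaults are filled in from `label`.
#' @param p_groups detection probabilities of the two latent groups
#'   (two-group scenario only).
#' @param mixture_weight probability that an individual belongs to group 1
#'   (two-group scenario only).
#'
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(label = c("symmetric", "right_skewed",
                                    "left_skewed", "two_group"),
                          n_occasions = 15, n_new_per_occasion = 50,
                          phi = 0.7, p_mean = NULL, p_sd = NULL,
                          p_groups = c(0.2, 0.8), mixture_weight = 0.5) {
  label <- match.arg(label)
  defaults <- list(symmetric    = c(0.4, 0.148),
                   right_skewed = c(0.2, 0.163),
                   left_skewed  = c(0.8, 0.163))
  if (label != "two_group") {
    if (is.null(p_mean)) p_mean <- defaults[[label]][1]
    if (is.null(p_sd))   p_sd   <- defaults[[label]][2]
  }
  # phi = 0 and 1 and p = 1 are admitted as degenerate simulation edges;
  # the canonical study scenarios use interior values
  stopifnot(phi >= 0, phi <= 1, n_occasions >= 2, n_new_per_occasion >= 1)
  if (label == "two_group") {
    stopifnot(length(p_groups) == 2, all(p_groups > 0), all(p_groups <= 1),
              mixture_weight > 0, mixture_weight < 1)
  } else {
    # moment validity is checked by beta_from_moments
    beta_from_moments(p_mean, p_sd)
  }
  structure(list(label = label, n_occasions = as.integer(n_occasions),
                 n_new_per_occasion = as.integer(n_new_per_occasion),
                 phi = phi, p_mean = p_mean, p_sd = p_sd,
                 p_groups = p_groups, mixture_weight = mixture_weight),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("CMR scenario '%s': K = %d occasions, %d new marks/occasion, phi = %g\n",
              x$label, x$n_occasions, x$n_new_per_occasion, x$phi))
  if (x$label == "two_group")
    cat(sprintf("  detection: two groups p = %g / %g, weight %g\n",
                x$p_groups[1], x$p_groups[2], x$mixture_weight))
  else
    cat(sprintf("  detection: beta with mean %g, SD %g\n", x$p_mean, x$p_sd))
  invisible(x)
}

#' The four canonical heterogeneity scenarios
#'
#' @param ... arguments passed on to every [scenario_spec()] call
#'   (e.g. `n_occasions`, `phi`) to override the study defaults.
#' @return Named list of four `scenario_spec` objects.
#' @export
cmr_scenarios <- function(...) {
  labs <- c("symmetric", "right_skewed", "left_skewed", "two_group")
  stats::setNames(lapply(labs, function(l) scenario_spec(l, ...)), labs)
}

#' Beta shape parameters from probability-scale moments
#'
#' Solves for the shapes `(alpha, beta)` of a beta distribution with the
#' given mean and standard deviation: with `k = mean(1-mean)/sd^2 - 1`,
#' `alpha = mean * k` and `beta = (1-mean) * k`. The variance bound
#' `sd^2 < mean(1-mean)` of the beta family must hold.
#'
#' @param mean probability-scale mean, in (0,1).
#' @param sd probability-scale standard deviation.
#' @return Named numeric vector `c(shape1, shape2)`.
#' @export
beta_from_moments <- function(mean, sd) {
  stopifnot(length(mean) == 1, length(sd) == 1)
  if (mean <= 0 || mean >= 1) stop("mean must lie in (0,1)")
  v <- sd^2
  if (v <= 0 || v >= mean * (1 - mean))
    stop(sprintf(
      "invalid beta moments (mean = %g, sd = %g): need 0 < sd^2 < mean*(1-mean) = %g",
      mean, sd, mean * (1 - mean)))
  k <- mean * (1 - mean) / v - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Generating probability-scale detection SD of a scenario
#'
#' The SD of the distribution of individual detection probabilities implied
#' by the scenario: `p_sd` for beta scenarios, the mixture SD
#' `sqrt(w*p1^2 + (1-w)*p2^2 - m^2)` for the two-group scenario.
#'
#' @param spec a [scenario_spec()].
#' @return numeric scalar.
#' @export
scenario_detection_sd <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$label != "two_group") return(spec$p_sd)
  w <- spec$mixture_weight; p <- spec$p_groups
  m <- w * p[1] + (1 - w) * p[2]
  sqrt(w * p[1]^2 + (1 - w) * p[2]^2 - m^2)
}

#' Generating probability-scale detection mean of a scenario
#' @param spec a [scenario_spec()].
#' @return numeric scalar.
#' @export
scenario_detection_mean <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$label != "two_group") return(spec$p_mean)
  w <- spec$mixture_weight
  w * spec$p_groups[1] + (1 - w) * spec$p_groups[2]
}

#' Draw per-individual detection probabilities under a scenario
#'
#' Beta scenarios draw i.i.d. values from the moment-matched beta
#' distribution; the two-group scenario assigns each individual to group 1
#' with probability `mixture_weight` and sets `p` to that group's value.
#'
#' @param spec a [scenario_spec()].
#' @param n number of individuals.
#' @param seed optional integer seed (`set.seed` is called when supplied).
#' @return data.frame with columns `p` and `group` (`NA` for beta scenarios).
#' @export
draw_individual_p <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (spec$label == "two_group") {
    g <- 1L + stats::rbinom(n, 1L, 1 - spec$mixture_weight)
    data.frame(p = spec$p_groups[g], group = g)
  } else {
    sh <- beta_from_moments(spec$p_mean, spec$p_sd)
    data.frame(p = stats::rbeta(n, sh[1], sh[2]), group = NA_integer_)
  }
}
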