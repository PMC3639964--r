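# hetcjs

Individual capture heterogeneity in Cormack–Jolly–Seber survival models.

## The problem

Open-population capture–mark–recapture (CMR) studies estimate apparent
survival φ jointly with the detection probability p of a marked animal that
is alive and present. Classical CJS fits assume every individual shares the
same p. Real populations rarely do: home ranges overlap a study area
unevenly, social status changes trappability, unrecognized groups mix in
the sample. Because the animals that are caught most are the easy-to-catch
ones, unmodelled heterogeneity pushes the detection estimate up and the
survival estimate down.

`hetcjs` is a simulation-and-inference toolkit for quantifying that bias
and for removing it with a logit-normal individual random effect on
detection. It is aimed at quantitative ecologists who want to (i) reproduce
the classical simulation experiment desk-side, (ii) run the same machinery
on their own capture histories (CSV or MARK-style `.inp`), and (iii) screen
data with U-CARE-style goodness-of-fit diagnostics before choosing a model.

## The model

State process (alive/dead, conditioned on first capture) and observation
process, per individual *i* and occasion *t*:

    z[i, t+1] | z[i, t] ~ Bernoulli(z[i, t] * phi)
    y[i, t]   | z[i, t] ~ Bernoulli(z[i, t] * p_i)

Heterogeneous detection is modelled on the logit scale,

    logit(p_i) = mu + eps_i,   eps_i ~ Normal(0, sigma^2),

and each individual's random effect is integrated out of the likelihood by
Gauss–Hermite quadrature, so both maximum-likelihood and MCMC fits work on
the exact marginal likelihood. Four canonical generating scenarios for
`p_i` are built in: symmetric beta (mean 0.4, SD 0.148), right-skewed beta
(0.2, 0.163), left-skewed beta (0.8, 0.163), and a two-group 0.2/0.8
mixture — all with φ = 0.7, 15 annual occasions and 50 newly marked
individuals per occasion.

The goodness-of-fit suite builds the m-array and the four CJS component
tests (TEST3.SR, TEST3.SM, TEST2.CT, TEST2.CL) with expected-count pooling,
directional z tests for transience and trap-dependence, and the
overdispersion factor ĉ = χ²/df.

## Worked example

```r
library(hetcjs)

spec <- scenario_spec("two_group")       # 0.2 / 0.8 detection mixture
ch   <- simulate_dataset(spec, seed = 42)

fit_c <- fit_cjs_mle(ch, "constant_p")   # ignores heterogeneity
fit_h <- fit_cjs_mle(ch, "re_p")         # logit-normal individual effect
```

```
CJS fit (mle, model 'constant_p'), 750 individuals x 15 occasions
  phi      0.6261 (se 0.0141)
  p        0.5719 (se 0.0216)
  logLik -1284.054
CJS fit (mle, model 're_p'), 750 individuals x 15 occasions
  phi      0.6640 (se 0.0172)
  p_mean   0.4929 (se 0.0405)
  sigma    1.4607 (se 0.2304)
  logLik -1266.058
```

The generating survival is 0.7. Ignoring the mixture biases φ̂ low (0.626)
and inflates p̂ (0.572 against a true mean of 0.5); the random-effects
model recovers φ̂ = 0.664 ± 0.017 and puts the fitted heterogeneity, via
`implied_detection_sd(fit_h$mu, coef(fit_h)["sigma"])`, at 0.267 on the
probability scale (generating SD 0.3). The diagnostics flag the
heterogeneity before any model is fitted:

```
print(overall_gof(ch))
CJS goodness-of-fit (TEST3.SR + TEST3.SM + TEST2.CT + TEST2.CL)
TEST3.SR: chi2 = 31.618, df = 13, p = 0.00274; directional z = 3.325 (p = 0.000885)
TEST3.SM: chi2 = 19.087, df = 15, p = 0.21
TEST2.CT: chi2 = 18.685, df = 11, p = 0.067; directional z = 3.062 (p = 0.0022)
TEST2.CL: chi2 = 5.413, df = 5, p = 0.368
Overall: chi2 = 74.803, df = 44, p = 0.00257; c-hat = 1.7
```

Positive directional z values read as apparent transience (TEST3.SR) and
trap-happiness (TEST2.CT) — both artifacts of heterogeneity here, since the
generator has neither.

Replicate studies aggregate this over scenarios and models:

```r
study <- run_replicate_study(cmr_scenarios(), n_replicates = 20,
                             engine = "mle", seed = 1)
bias_report(study)          # phi bias/precision + detection-SD bias
precision_comparison(study) # paired SD comparison between the two models
```

A Bayesian engine (`engine = "mcmc"`, componentwise random-walk Metropolis,
U(0,1)/U(0,10) priors, default single chain of 30000 iterations with
burn-in 20000 and thinning 10) mirrors the classical protocol;
`fit_cjs_mcmc(..., chains = 3)` adds Brooks–Gelman–Rubin convergence
statistics. `run_study("config.yaml", out_dir)` drives the whole pipeline
from a YAML/JSON configuration, and `inst/cli/hetcjs.R` exposes
`simulate | fit | gof | study` subcommands for shell use.

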