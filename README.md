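# mggp — multi-group Gaussian process regression

Grouped regression data are everywhere in biostatistics: samples carry
continuous features `x1..xp`, a label from a finite set of groups (tissue,
cohort, site, arm), and a response `y`. Groups are related to different
degrees and their sample sizes are often imbalanced. The classical options
are extremes: a *separate* GP per group (SGP, no sharing), one *union* GP
over all samples (UGP, no group structure), or a *hierarchical* GP (HGP,
a shared kernel plus a same-group bonus). **mggp** implements the
multi-group Gaussian process: a single GP on the product space
ℝᵖ × {groups} whose covariance function couples the two coordinates
nonseparably,

    K{(x, cᵢ), (x′, cⱼ)} = σ² ψ(d²ᵢⱼ)^(−p/2) · φ(‖x − x′‖² / ψ(d²ᵢⱼ)),

with φ completely monotone, ψ positive with completely monotone
derivative, and d a metric between groups (discrete metric by default;
validity is certified through the positive semi-definiteness of the Gram
matrix derived from d). The workhorse member is the multi-group RBF

    K = σ² (a²d²ᵢⱼ + 1)^(−p/2) · exp{ −b²‖x − x′‖² / (a²d²ᵢⱼ + 1) },

where `a ≥ 0` is the **group similarity scale**: `a = 0` recovers the
union GP, `a → ∞` the separate GPs, and everything in between is a
data-estimable degree of sharing. Multi-group Matérn and exponential
families, separable kernels, the three baselines, spectral
positive-definiteness certificates, collapsed-likelihood regression,
maximum-likelihood and fully Bayesian inference (adaptive
Metropolis-within-Gibbs with conjugate intercept draws), posterior
prediction, and the simulation studies are all included. Everything is
tidyverse-shaped: data frames in, tibbles out, `tidy()`/`glance()` on
fitted objects, `autoplot()` on results.

## Worked example

Simulate two related groups from the multi-group RBF process (true
σ² = a = b = 1, noise variance 0.1), then re-estimate all parameters by
maximizing the collapsed likelihood:

```r
library(mggp)

d <- simulate_mggp(model = "mggp", n_per_group = c(60, 60),
                   a = 1, b = 1, sigma2 = 1, tau2 = 0.1, seed = 42)
fit <- fit_mle(d, "mg_rbf", restarts = 3)
fit
#> <mggp_mle> family=mg_rbf, logLik=-66.0518 (converged)
#>   sigma2=0.4873, a=1.34, b=1.193, tau2=0.09305
```

The group-similarity estimate `a ≈ 1.34` recovers the generating value 1
(σ² and b trade off against each other, as usual for GP scale parameters,
so their individual estimates are less pinned down than their product).
Profiling the likelihood over `a` with the other parameters held at truth
shows the same story — the curve is flat toward the union-GP limit, rises
to its peak at the generating value, and drops toward the separate-GP
plateau:

```r
profile_loglik_a(d, fixed = list(sigma2 = 1, b = 1, tau2 = 0.1))
#> # A tibble: 8 × 2
#>           a log_lik
#>       <dbl>   <dbl>
#> 1   0.00001   -99.4
#> 2   0.0001    -99.4
#> 3   0.001     -99.4
#> 4   0.01      -99.3
#> 5   0.1       -92.9
#> 6   1         -67.9
#> 7  10         -71.1
#> 8 100         -71.4
```

A fully Bayesian fit with the package's default priors (inverse-gamma on
the kernel scales, Gaussian on group intercepts, IG(5,5) on the noise
*standard deviations*) is one call — `bayes_fit(d)` — and returns draws,
R-hat/ESS diagnostics and `tidy()` posterior 50 (2.5; 97.5) percentile
summaries. `pairwise_a()` runs the two-group fit for every pair of groups
and collects the similarity estimates; `run_model_comparison()`,
`run_mle_recovery()`, `run_prediction_benchmark()`,
`run_imbalanced_groups()` and `run_bayes_study()` reproduce the simulation
studies at configurable scale, each with an `autoplot()` method. A thin
command-line front end over the same functions is installed at
`inst/scripts/mggp.R` (subcommands `simulate`, `fit-mle`, `fit-bayes`,
`profile-a`, `pairwise-a`, `predict`, `exp-*`).

See the methods vignette (`vignettes/multi-group-gps.Rmd`) for the model,
the kernel constructions and their validity certificates, all numerical
and protocol choices, and known limitations.

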