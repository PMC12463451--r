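---
title: "Multi-group Gaussian processes: model, kernels, and inference choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-group Gaussian processes: model, kernels, and inference choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mggp)
```

## The model

Many regression problems in biostatistics arrive as grouped tables: samples
carry continuous features $x \in \mathbb{R}^p$, a label $c_j$ from a finite
set of $k$ groups (tissues, cohorts, sites, treatment arms), and a real
response $y$. Groups may be related — some pairs strongly, others hardly at
all — and per-group sample sizes are often badly imbalanced. Fitting one
Gaussian process per group (the *separate* GP, SGP) ignores shared
structure; pooling everything into one GP (the *union* GP, UGP) ignores
group differences; adding a same-group covariance bonus (the *hierarchical*
GP, HGP) interpolates between the two but with a fixed, label-blind notion
of relatedness.

The multi-group GP (MGGP) instead defines a single latent process on the
product space $\mathbb{R}^p \times \mathcal{C}$:

$$y(x; c_j) = \beta_j + Z(x; c_j) + \epsilon, \qquad
  \epsilon \sim N(0, \tau_j^2),$$

where $Z$ is a zero-mean GP whose covariance function couples the
continuous and categorical coordinates *nonseparably*. All group structure
lives in the kernel, so every standard GP computation — marginal
likelihood, conditioning, posterior prediction — applies unchanged.

## Kernels

The package's multi-group kernels are Gneiting-class constructions

$$K\{(x, c_i), (x', c_j)\} =
  \frac{\sigma^2}{\psi(d_{ij}^2)^{p/2}}\,
  \varphi\!\left(\frac{\|x - x'\|^2}{\psi(d_{ij}^2)}\right),$$

with $\varphi$ completely monotone, $\psi$ positive with completely
monotone derivative (the menu of both is in `monotone_pair()`), and
$d_{ij}$ a metric between groups. Validity requires the Gram matrix
$G_{ij} = \tfrac12\{d(c_1,c_i) + d(c_1,c_j) - d(c_i,c_j)\}$ to be positive
semi-definite; `mggp_groups()` certifies this at construction, with the
noninformative discrete metric $d_{ij} = 1 - \delta_{ij}$ as the default.
The anchor $c_1$ is the first label in user order; positive
semi-definiteness does not depend on the anchor (tested).

Three named families cover the common cases:

* `mg_rbf` — $\sigma^2 (a^2 d_{ij}^2 + 1)^{-p/2}
  \exp\{-b^2\|x-x'\|^2/(a^2 d_{ij}^2 + 1)\}$;
* `mg_matern` — with $u = a^2 d_{ij}^2 + 1$, $v = a^2 d_{ij}^2 + c$ and
  $z = b\sqrt{u/v}\,\|x - x'\|$:
  $\sigma^2 c^{p/2} u^{-\nu} v^{-p/2} M_\nu(z)$, where
  $M_\nu(z) = 2^{1-\nu}\Gamma(\nu)^{-1} z^\nu K_\nu(z)$;
* `mg_exponential` — the $\nu = 1/2$ case in closed form.

The Matern form is pinned by three requirements rather than transcribed
from a single display: it must reduce exactly to the exponential family at
$\nu = 1/2$, factorize into a (space) $\times$ (group) product at $c = 1$,
and be the standard Matern within a group ($d_{ij} = 0$). The implementation
satisfies all three to $10^{-10}$ relative tolerance (tested), which pins
the formula uniquely within the family.

Parameter meanings and units: $\sigma^2$ is the latent variance (response
units squared), $b$ an inverse length scale of the features, $a \ge 0$ the
**group similarity scale** — the single most interpretable quantity in the
package. At $a = 0$ groups are indistinguishable (UGP limit); as
$a \to \infty$ cross-group covariance vanishes (SGP limit). $\nu$ is held
fixed by default (`nu = 1.5`) and not estimated: smoothness estimation is
notoriously ill-posed and none of the package's study designs attempt it.
$c \in (0, \infty)$ trades off space–group separability in the
Matern/exponential families (exactly separable at $c = 1$).

Baselines are expressed in the same kernel container: `sgp`, `ugp`, and
`hgp`. The hierarchical baseline uses **one RBF for both of its
components** (shared $\sigma^2$ and $b$; within-group variance $2\sigma^2$,
cross-group $\sigma^2$), matching the convention of the package's
comparison studies; `mggp_kernel()` accepts general `k0`/`k1` components
for users who want the freer four-parameter variant.

## Validity certificates

Beyond the constructive guarantee, two numerical certificates are exposed.
For the RBF family the two-group spectral densities are closed-form
Gaussians,
$\rho_w(\omega) = \sigma^2 (\pi/b^2)^{p/2} e^{-\pi^2\|\omega\|^2/b^2}$ and
$\rho_c(\omega) = \sigma^2 (\pi/b^2)^{p/2}
e^{-\pi^2 (a^2+1)\|\omega\|^2/b^2}$ (the cross density was re-derived by
Fourier-transforming the cross-group kernel slice; the dominance
$\rho_w \ge \rho_c$ holds for every $a \ge 0$). `check_two_group_stationary()`,
`check_semistationary()` ($\rho_0\rho_1 \ge \rho_c^2$) and `check_k_group()`
(pointwise PSD of the $k \times k$ density matrix) verify dominance on a
frequency grid — 201 points per axis over $[-5b, 5b]$ by default, which
covers the effective support of these Gaussian densities — with a relative
tolerance of $10^{-10}$, since strict pointwise inequalities are
unverifiable in floating point. Kernels without closed-form densities are
checked by the matrix eigenvalue oracle `is_psd_matrix()` (minimum
eigenvalue $\ge -10^{-8}\times$ the largest diagonal entry, the usual
allowance for eigensolver noise on rank-deficient matrices).

## Regression machinery

With group-intercept design matrix $F$ ($n \times k$, one indicator column
per group) and noise matrix $D_\tau$, the collapsed marginal likelihood is
$\log N(y \mid F\beta, K_\theta + D_\tau)$, evaluated by Cholesky
factorization throughout ($O(n^3/3)$, no explicit inverses). The latent
posterior is Gaussian with covariance $M = (K^{-1} + D_\tau^{-1})^{-1}$ and
mean $M D_\tau^{-1}(y - F\beta)$, computed in the stable equivalent forms
$K - K(K+D_\tau)^{-1}K$ and $K(K+D_\tau)^{-1}(y - F\beta)$. (A common
shorthand writes the mean as "$Mm$" with $m = y - F\beta$; the
$D_\tau^{-1}$ factor is required for the interpolation limit
$\tau^2 \to 0 \Rightarrow \text{mean} \to y - F\beta$ to hold, and that
limit is what the package tests.)

Point prediction follows the conditional-mean formula
$\mu^\star = K_{X^\star X} K_{XX}^{-1} y$ on group-centered responses.
`predict_gp_mean()` exposes both the noise-free version (the formula as
written; the default) and a variant adding $\tau^2$ to the diagonal of
$K_{XX}$ (`include_noise = TRUE`), which conditions on noisy observations
instead of interpolating them. The experiment drivers use the noisy
variant, since they fit $\tau^2$ and the simulated responses are noisy.

Degenerate inputs: duplicated rows make $K$ singular, so `kernel_matrix()`
adds a jitter of $10^{-8}\sigma^2$ and escalates it tenfold up to
$10^{-4}\sigma^2$ before failing with the offending minimum eigenvalue.
Spatial distances below $10^{-12}$ are routed to the exact $x = x'$ branch
of the Matern (the Bessel function $K_\nu$ is singular at zero).

## Maximum likelihood

`fit_mle()` maximizes the collapsed likelihood jointly over the free
kernel parameters, noise variance(s) and optional intercepts, in
log-transformed space for everything positive — estimates can never
violate positivity, and no box constraints are needed. The surface is
multimodal in $a$ (a flat ridge toward the UGP limit is common), so the
optimizer restarts from log-uniform draws over $[10^{-2}, 10]$ and keeps
the best run. Gradients are analytic for the RBF-based families and checked
against central finite differences to $10^{-5}$ relative tolerance in the
test suite; the Matern/exponential/generic families fall back to central
differences.

Two protocol details of the recovery studies are worth stating. First,
`run_mle_recovery()` pins $b, \sigma^2, \tau^2$ to their generating values
and profiles over $a$ alone — the protocol of a single-parameter recovery
figure; joint estimation remains available (`pin_others = FALSE`). Second,
identifiability of small $a$ is intrinsically poor: the cross-group
covariance perturbation is $O(a^2)$, so at the study's sample sizes truths
of $10^{-3}$ and $10^{-2}$ are statistically indistinguishable and both
estimate near the UGP ridge; the recovery summary's monotonicity refers to
medians across replicates and tolerates this flatness at the low end.

## Bayesian inference

Priors (`mggp_priors()`): inverse-gamma on $a$, $b$ (shape = scale = 5)
and $\sigma^2$ (shape = scale = 1); Gaussian $N(0, I)$ on the intercepts.
The noise prior is IG(5, 5) **on the noise standard deviation**
$\tau_j$, not the variance. This is a deliberate parameterization choice:
an IG(5, 5) prior placed directly on $\tau_j^2$ acts like ten pseudo-
observations of unit variance, and with a couple of hundred samples of true
variance $0.1$ the posterior cannot reach the truth — its 2.5% quantile is
pinned near $0.14$ regardless of the data, and simulation coverage of
$\tau_1^2 = 0.1$ collapses to zero. On the SD scale the same
hyperparameters are only mildly informative, the posterior tracks the data
(medians near $0.11$ for $\tau_1^2$ in the package's coverage study), and
interval coverage behaves like a 95% interval should. The variance-scale
option is retained (`tau_prior_on = "variance"`).

`bayes_fit()` samples the collapsed posterior with adaptive
Metropolis-within-Gibbs: component-wise random-walk proposals on
$\log a, \log b, \log \sigma^2, \log \tau_j^2$ (step sizes tuned toward 44%
acceptance during warmup, then frozen, so the retained chain has a fixed
transition kernel and the correct stationary distribution) and an exact
conjugate Gaussian draw for $\beta$ each sweep. Chains are seeded
`seed + chain - 1`, making runs reproducible draw-for-draw. Convergence is
summarized with Gelman–Rubin $\widehat{R}$ and effective sample sizes from
**coda**; $\widehat{R} > 1.1$ is recorded on the result object, never
raised as an error. A prior-only mode (`likelihood = FALSE`) exists purely
so the sampler can be validated against closed-form inverse-gamma
quantiles, which the test suite does.

Posterior prediction (`sample_latent_and_predict()`) follows the
hierarchical path draw by draw: latent vector from $N(M D_\tau^{-1} m, M)$,
latent value at each new point from the noise-free conditional, response
draw adding $\beta_j$ and $N(0, \tau_j^2)$ noise.

## The synthetic-data generator

`simulate_mggp()` draws the latent vector jointly from the exact
finite-dimensional law of the configured process (Cholesky of the full
kernel matrix over all groups), then adds intercepts and Gaussian noise.
Inputs are uniform on per-group intervals, default $[-5, 5]$ for every
group. Continuous sampling means design points are almost never shared
across groups — each $x$ is observed for one group only, the partially
observed-coordinates regime; per-group ranges can also be offset to make
supports fully disjoint. Defaults mirror the package's study conditions:
$\sigma^2 = a = b = 1$, $\tau^2 = 0.1$, two groups of 100.

What the generator does *not* emulate: non-Gaussian noise, heteroscedastic
noise within a group, covariate-dependent group membership,
non-stationarity in $x$, and model misspecification of the kernel family
itself. Passing tests therefore certify internal correctness (draws have
the advertised covariance; estimators recover generating parameters;
credible intervals are calibrated *under the model*) — they do not certify
that any real dataset follows an MGGP.

## Study designs and their sizes

The experiment drivers reproduce the package's simulation studies at desk
scale; sizes below were chosen once as the package's study conditions.

* **Likelihood comparison** (`run_model_comparison()`): two groups of 100,
  20 replicates, all parameters pinned to truth, $a$ swept over
  $10^{-5}, \dots, 10^2$. Bands in the plot are normal-approximation 95%
  intervals on the replicate mean.
* **Recovery** (`run_mle_recovery()`): truths
  $a \in \{10^{-3}, 10^{-2}, 10^{-1}, 1\}$, two groups of 100, 10
  replicates.
* **Bayesian coverage** (`run_bayes_study()`): $\beta = (1, 2)$,
  $\tau^2 = (0.1, 0.3)$, $\sigma^2 = a = b = 1$, two groups of 100, 4
  chains; the package's acceptance run uses 200 warmup and 500 retained
  draws per chain (a scaled-down schedule; the samplers mix well before
  200 iterations on these data), 10 replicates.
* **Prediction benchmark** (`run_prediction_benchmark()`): two groups of
  30 (15 training points per group after the 50% split), 20 replicates.
  The size is deliberately small: with 50 training points per group every
  model sits at the noise floor $\tau^2$ and predictive differences are
  unresolvable; at 15 points per group the value of sharing strength
  across groups is visible.
* **Imbalanced groups** (`run_imbalanced_groups()`): three groups with
  distances $d(c_1, c_2) = 0.1$ and $d(\cdot, c_3) = 1$ — similarity
  encoded through the package's own metric machinery — sizes
  $n_1 \in \{5, 10, 30, 50\}$, $n_2 = n_3 = 50$.

Two benchmark protocol choices deserve emphasis. **Centering**: the
drivers remove each group's mean from the *full dataset* before the
train/test split (`centering = "dataset"`). Centering by training-half
means only (`"training"`) is also available; it leaks no information, but
the extra level noise it injects is largest for exactly the models that
share strength across groups, and at small $n$ it can erase the true
model's advantage. **Parameters**: by default the predictors are
conditioned with kernel parameters at their generating values
(`fit_mode = "pinned"`), the same convention as the likelihood comparison,
under which the generating model's predictor is the Bayes rule and the
expected ordering is a population-level fact. `fit_mode = "mle"`
re-estimates every model's parameters on the training half; at 15 training
points per group the $\hat a$ of the multi-group fit occasionally
collapses onto the UGP ridge, inflating its average error — an instructive
display of small-sample estimation fragility, not of predictive ranking.

## Pairwise group similarity

`pairwise_a()` restricts the data to each unordered pair of groups, fits
the multi-group model with $(a, b, \sigma^2, \tau^2)$ free, and collects
$\hat a$ — small values flag pairs that share structure. For $k$ groups
this is $k(k-1)/2$ fits (1,326 at $k = 52$); pairs with fewer than three
samples in either group are flagged and skipped, and `fit = FALSE`
enumerates without fitting.

## Known limitations

* Dense Cholesky limits practical $n$ to a few thousand; no low-rank or
  sparse approximations are provided.
* The group metric is fixed, not learned.
* $\nu$ estimation is not attempted; $c$ is estimated only when the
  Matern/exponential families are selected.
* The random-walk sampler is adequate for the handful of kernel
  parameters used here but would mix poorly in higher-dimensional
  parameterizations; the sampler contract (correct stationary
  distribution) is what the package tests.
* Single-output responses only; no multivariate extension.
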