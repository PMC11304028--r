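---
title: "Methods: the modified Weibull model under progressive first-failure censoring"
author: "mwpffc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the modified Weibull model under progressive first-failure censoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwpffc)
```

## The model

The modified Weibull distribution (MWD) has density

$$f(x) = \lambda\alpha\,(x/\beta)^{\alpha-1}
  \exp\!\big\{(x/\beta)^\alpha + \lambda\beta\,(1 - e^{(x/\beta)^\alpha})\big\},
  \qquad x > 0,$$

with shape parameters $\alpha, \beta > 0$ and scale $\lambda > 0$. Its
hazard $h(t) = \lambda\alpha (t/\beta)^{\alpha-1} e^{(t/\beta)^\alpha}$ is
increasing for $\alpha \ge 1$; for $\alpha < 1$ it is bathtub-shaped with
interior minimum at $t^* = \beta((1-\alpha)/\alpha)^{1/\alpha}$, obtained by
solving $d\log h/dt = 0$ (`mwd_hazard_min()`). All evaluation is done in
log space — $(x/\beta)^\alpha$ as $\exp\{\alpha \log(x/\beta)\}$, the
density as $\exp(\log f)$ — so large $t/\beta$ underflows gracefully
instead of producing `NaN`.

Two degenerate directions of the parameter space drive much of what
follows:

* at $\lambda = 1$ the MWD is the exponential power distribution;
* as $\beta \to \infty$ with $\theta = \lambda\beta^{1-\alpha}$ held fixed,
  $F(x) \to 1 - e^{-\theta x^\alpha}$: **the Weibull family sits on the
  boundary of the MWD**, and the profile log-likelihood is asymptotically
  flat along that ridge.

## Progressive first-failure censoring

$n$ groups of $k$ units are tested; at the $i$-th observed first failure,
$R_i$ surviving groups are withdrawn, leaving $m$ ordered first-failure
times with $\sum R_i = n - m$. The conventional removal patterns SC1 / SC2
/ SC3 put all $n-m$ removals at the first, middle, or last failure. For SC2
with even $m$ and odd $n - m$ the removal is split
$\lfloor(n-m)/2\rfloor$ / $\lceil(n-m)/2\rceil$ across the two middle
positions with a warning, so simulation grids are not artificially
restricted to divisible cases.

Sampling (`rpffc`) follows the Balakrishnan–Sandhu construction applied to
the first-failure law $1-(1-F)^k$: from $W_i \sim U(0,1)$,
$V_i = W_i^{1/(i + R_m + \cdots + R_{m-i+1})}$,
$U_i = 1 - V_m V_{m-1}\cdots V_{m-i+1}$ is a progressive Type-II uniform
sample, and $X_i = F^{-1}(1 - (1-U_i)^{1/k})$ via the closed-form quantile
function. The test suite checks the implied laws directly: the smallest
observation follows $1-(1-F)^{nk}$, and $k=1$, $R=0$, $m=n$ reduces to
complete-sample order statistics (Kolmogorov–Smirnov over 2000
replications). These checks are not decorative — they caught a wrong
product ordering in the $U_i$ recursion during development.

## Likelihood, score, and fitting

Writing $z_i = (x_i/\beta)^\alpha$, the PFFC log-likelihood implemented in
`pffc_loglik()` is

$$\ell = m\log(\alpha\lambda) + (\alpha-1)\sum\log(x_i/\beta) + \sum z_i
 + kn\lambda\beta - k\lambda\beta\sum (R_i+1)e^{z_i},$$

which the tests verify is exactly
$\sum \log f(x_i) + \sum[k(R_i+1)-1]\log S(x_i)$ up to parameter-free
constants. The analytic score (`pffc_score`) is cross-checked against
central finite differences on random parameter/sample pairs at
$10^{-6}$ relative tolerance; $\partial^2\ell/\partial\lambda^2 =
-m/\lambda^2$ is checked exactly. The $\lambda$ score has the closed-form
root

$$\hat\lambda(\alpha, \beta) =
  \frac{m}{k\beta \sum (R_i+1)(e^{z_i}-1)},$$

so `mwd_fit()` reduces the problem to $(\alpha, \beta)$, searched in log
coordinates by Nelder–Mead and polished by a joint BFGS step with the
analytic gradient. The covariance is the inverse observed information
(finite differences of the analytic score, symmetrized), Wald intervals are
$\hat\theta \pm z_{\gamma/2}\sqrt{v_\theta}$ (untruncated by default, with
a `truncate` option), and intervals for $S(t)$, $h(t)$, $r(t)$ use the
delta method with numerically differentiated gradients. A delta variance
for $S(t)$ was checked against a 300-replicate parametric bootstrap at
$(n,m) = (90,75)$: ratio 0.94.

**Why the default fit is local, not global.** Because the Weibull family
sits on the $\beta\to\infty$ boundary, samples that happen to look
Weibull-like (and at some truths, *most* samples) give the global maximum
to a near-Weibull representation with large $\alpha$ or runaway $\beta$
rather than to the interior mode near the data-generating parameters. In a
Monte-Carlo experiment at truth $(1, 0.1, 2)$, chasing the global optimum
put $\hat\alpha$ between 6 and 30 in roughly half the replicates and
destroyed interval coverage. The default is therefore the classical local
fit from the crude initialization $\alpha = 1$, $\beta = \mathrm{median}(x)$
— the same practice as the Newton–Raphson solvers traditionally used for
this design — with `multistart = TRUE` available when the global optimum is
genuinely wanted. Fits escaping the ridge ($\hat\beta > 100\max x_i$, or
$\hat\alpha,\hat\lambda$ outside $[10^{-3}, 10^{3}]$) are flagged
`converged = FALSE` rather than returned silently.

## Bayes estimation

Independent gamma priors $\pi(\theta_i) \propto \theta_i^{a_i-1}
e^{-b_i\theta_i}$ are assumed; all-zero hyperparameters give the
scale-invariant Jeffreys-type prior. Two loss functions are supported:
squared error (posterior mean) and general entropy,
$\hat g = [E(g^{-\epsilon})]^{-1/\epsilon}$, which coincides with the
posterior mean at $\epsilon = -1$. In both the Lindley and MCMC code paths
the $\epsilon=-1$ case reuses the squared-error computation verbatim, so
the coincidence is bit-exact by construction.

**Lindley approximation.** `mwd_lindley()` evaluates the second-order
expansion of $E[w(\theta)\,|\,\text{data}]$ around the MLE,

$$E[w] \approx w + \sum_{ij}\Big(\tfrac{1}{2}w_{ij} + w_i\rho_j\Big)\tau_{ij}
 + \tfrac{1}{2}\sum_{ijdl} \ell_{ijd}\,\tau_{ij}\tau_{dl}\,w_l,$$

with $\tau$ the inverse negative likelihood Hessian, $\rho = \log\pi$
gradients, and third derivatives $\ell_{ijd}$ by high-order finite
differences of the analytic score. Some presentations drop the $\tfrac12$
on the third-derivative term; validated against a model with an exact
conjugate posterior (three independent gamma-likelihood components), the
$\tfrac12$ is required, and the implementation reproduces the exact
posterior means within 3% there, with corrections scaling as $1/m$ as
information grows. **Limitation:** for the MWD itself at small or moderate
$m$ the likelihood is so diffuse (the $\lambda$–$\beta$ ridge again) that
the correction terms can exceed the estimates; the function computes
faithfully, but such output should not be trusted, and the test suite
deliberately validates the expansion on the conjugate surrogate rather
than pretending accuracy on diffuse MWD posteriors.

**MCMC.** `mwd_mcmc()` is a Metropolis-within-Gibbs sampler: $\lambda$ has
the conjugate conditional
$\mathrm{Gamma}\big(m+a_3,\; b_3 + k\beta\sum(R_i+1)(e^{z_i}-1)\big)$,
drawn exactly each sweep, while $\alpha$ and $\beta$ take normal
random-walk Metropolis steps with proposal standard deviations defaulting
to the Wald standard errors (10% of the current value, with a warning, if
the information matrix is not positive definite). Chains start at the MLE;
nonpositive proposals are rejected through a zero target density, the
simplest correct kernel on the half-line. The unnormalized conditionals are
tested to equal the joint log posterior up to constants at $10^{-10}$ — the
guard against kernel transcription errors — and the sampler's stationary
distribution is validated against 3-D grid quadrature of the posterior on
a small fixed problem (posterior means agree to well under 5%, split
Gelman–Rubin over four seeds below 1.05). Credible intervals use the
percentile construction on sorted post-burn-in draws (order statistics
$\lfloor\gamma(N-M)\rfloor$ and $\lceil(1-\gamma)(N-M)\rceil$), with an
optional non-default HPD mode (shortest interval over the sorted draws).

## The Monte-Carlo engine

`pffc_study()` replicates the full pipeline over a grid of designs and
schemes and reports, per quantity and estimator: mean squared error,
average interval length, and coverage probability, defined as the fraction
of intervals containing the **true** value (the only non-degenerate
reading; an interval trivially contains its own point estimate).
Replicates whose fit fails or escapes to the Weibull ridge are excluded
and counted (`n_failed`), never fabricated. Reproducibility: replicate $r$
of cell $c$ uses a deterministic child seed of the master seed, so results
are independent of execution order. Inside the study the chain length
defaults to 3000/500 (vs 12000/2000 standalone) to keep grids affordable;
this is a fidelity/runtime trade documented here rather than hidden.

## What the synthetic world does and does not establish

The generator draws exactly from the stated model under the stated scheme,
so green sampler tests establish distributional correctness of the design
simulation, and green study tests establish the estimators' behaviour
*under the model*. They do not establish robustness to misspecification,
tied or rounded recording of times, or dependence within groups — all
features real reliability data may have and the first-failure model
assumes away.

## Reproduction audit of the published analysis

The package was built against a published analysis of this design, and the
spec that derived from it flags several of its printed values as
typographical or internally inconsistent. Running the package honestly:

* The printed subsample estimates $(0.65122, 1.77911, 0.09011)$ are not a
  stationary point of the PFFC likelihood (the analytic score there is
  $(-15.7, 0.66, 2.9)$); the likelihood's interior optimum on the printed
  subsample is $(0.405, 3.892, 0.0635)$ with a log-likelihood 2.5 units
  higher. The printed triple also does not solve the published (typo-laden)
  score equations. The acceptance test for this target is left failing with
  the computed values in its message.
* The printed goodness-of-fit pair "$D = 0.3571$, $p = 0.092661$" for the
  100-point data set is these two numbers transposed: the package computes
  $D = 0.0927$, $p = 0.357$.
* The printed simulation-table MSEs are not recovered by an honest
  1000-replicate study at the stated truth, and 95% Wald coverage for
  $\alpha$ at the largest design comes out near 0.90 rather than the
  printed 0.996 — consistent with the skewed, weakly identified likelihood
  described above.

## Numerical choices

* Optimization in $\log$ parameters; `optim` Nelder–Mead
  (`reltol = 1e-12`) then BFGS (`reltol = 1e-14`) with analytic gradients.
* Observed information: central differences of the analytic score, relative
  step $10^{-5}$, symmetrized; singular matrices fall back to a
  pseudo-inverse with a warning flag carried into downstream methods.
* Lindley derivatives: relative steps $10^{-4}$ (second order) and
  $10^{-3}$ (third order).
* Quantile and CDF are exact closed forms; round-trip accuracy is tested at
  $10^{-10}$ over $u \in [10^{-6}, 1-10^{-6}]$.
* Density at $x = 0$: $0$ for $\alpha > 1$, $\lambda$ for $\alpha = 1$, and
  the true limit `Inf` (a documented sentinel, not an error) for
  $\alpha < 1$, so plotting code can cope.
* `qmwd` follows the half-open convention $u \in [0, 1)$ and rejects
  $u = 1$.

## Known limitations

* No Type-I or hybrid progressive variants, no random (binomial) removals.
* No exact small-sample confidence intervals; Wald intervals inherit the
  skewness problems documented above.
* Lindley output is untrustworthy for diffuse posteriors (small $m$), by
  the nature of the expansion.
* The K-S p-value ignores parameter estimation (no Lilliefors-type
  correction), matching the published procedure; it is anti-conservative
  as a goodness-of-fit test after fitting.
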