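---
title: "Bayesian dose-response modelling and synergy decoupling with dosebayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian dose-response modelling and synergy decoupling with dosebayes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosebayes)
```

## The problem

High-throughput drug-combination screens produce, for each drug pair and
cell line, a small dose-response matrix: one base well at dose zero, a
monotherapy row and column, and a grid of combination wells, with responses
on a normalised inhibition scale where the base value is about 100 and an
effective treatment drives the response towards 0. Two questions matter for
taking a combination forward: does combining the drugs increase the maximal
achievable effect (**synergistic efficacy**), and does it reduce the dose
needed to achieve a given effect (**synergistic potency**)? With 15-36
noisy wells per matrix, any point estimate of these quantities carries
substantial uncertainty, and downstream decisions (which combinations to
re-screen, which to advance) need that uncertainty quantified, not hidden.

`dosebayes` treats the whole problem as Bayesian inference in a parametric
dose-response model: the posterior distribution over the model parameters
induces posterior distributions — and hence credible intervals and tail
probabilities — for every quantity of interest.

## The model

**Monotherapy.** The expected response follows the four-parameter Hill
equation

$$E(x) = E_0 + \frac{E_1 - E_0}{1 + (C/x)^H},$$

with base level $E_0 = E(0)$, maximal-effect level $E_1 = E(\infty)$
(Einf), IC50 $C$ and slope $H$; observed responses are conditionally
independent Gaussians, $y \sim N(E(x), \sigma^2)$ (screening wells are run
on separate plates). At $x = 0$ the curve equals $E_0$ by the limit
convention; internally the fraction is evaluated as
$\mathrm{logit}^{-1}(H(\log x - \log C))$, which avoids division by zero
and stays finite for extreme slopes.

**Combination.** For two drugs the expected response is the
detailed-balance surface

$$E(x_1,x_2) = \frac{C_1^{H_1}C_2^{H_2}E_0 + x_1^{H_1}C_2^{H_2}E_1 +
C_1^{H_1}x_2^{H_2}E_2 + \alpha\, x_1^{H_1}x_2^{H_2}E_3}
{C_1^{H_1}C_2^{H_2} + x_1^{H_1}C_2^{H_2} + C_1^{H_1}x_2^{H_2} +
\alpha\, x_1^{H_1}x_2^{H_2}},$$

a weighted average of the four asymptotic levels $E_0=E(0,0)$,
$E_1=E(\infty,0)$, $E_2=E(0,\infty)$, $E_3=E(\infty,\infty)$. Each
monotherapy slice reduces exactly to the single-drug Hill curve, and the
association parameter $\alpha$ only acts where both doses are positive.
This single parameterisation spans the nested family of simpler
detailed-balance surfaces (no interaction, one-sided interaction, ...), so
the posterior covers them all at once and no post-hoc model selection is
needed. The package computes the surface through log-scale weights
normalised by their maximum, so it stays finite even when $x/C$ spans many
orders of magnitude or $H$ is large.

**Synergy summaries.** Per posterior draw,

* $\Delta\mathrm{HSA} = \min(E_1, E_2) - E_3$: the gain in maximal effect
  over the more effective single agent (on the decreasing-response scale
  the more effective drug has the *lower* level, hence the minimum).
  $P(\Delta\mathrm{HSA} > 0 \mid D)$ is the posterior probability of
  synergistic efficacy.
* $\alpha > 1$ means each drug potentiates the other;
  $P(\alpha > 1 \mid D)$ is the posterior probability of synergistic
  potency.

Both probabilities are exact empirical fractions over the retained draws
with strict inequalities (draws exactly at the boundary count as
non-synergistic), never kernel-smoothed: smoothing is a visualisation
device and would perturb the reported numbers. Because the minimum in
$\Delta\mathrm{HSA}$ is taken per draw, it respects the joint posterior
rather than combining marginal summaries.

## Priors

`prior_config()` holds the constants; the defaults are intended for
DREAM-convention inhibition data (base value $B = 100$):

| parameter | prior | rationale |
|---|---|---|
| $E_0$ | $N(B,\ 0.03B)$ (variance, so s.d. $\approx 1.73$ at $B=100$) | normalisation itself is a noisy measurement |
| $E_i/E_0$ | $U(0,1)$ or $\mathrm{Beta}(0.46, 0.58)$ | normalised efficacy in $[0,1]$; the Beta option is an empirical single-agent prior, bimodal at the extremes (a drug at saturating dose is typically either very effective or inactive) |
| $\log C$ | $U(\log\delta, \log M)$ | uninformative over potency; an IC50 outside the tested dose range must stay possible a priori |
| $H,\ \sigma$ | lognormal(0, 1) | positive and moderately small; $P(H<5) \approx 0.95$ |
| $\alpha$ | lognormal(0, 1) | positive with median exactly 1 = no potency interaction |

The efficacy priors are hierarchical: $E_0$ is drawn first, then the ratio
$E_i/E_0$; expressed as a density in $E_i$ this contributes a $1/E_0$
Jacobian, which `log_prior_mono()`/`log_prior_combo()` include. The bounds
$\delta < M$ live on the raw dose scale; the package-wide defaults are
$\delta = 10^{-10}$, $M = 10^6$ (suitable for micromolar dose units), and
`prior_from_data()` adapts them to a dataset as half the smallest non-zero
dose and ten times the largest dose. Responses are modelled on the raw
normalised scale (0-100-ish), not rescaled to the unit interval, since $B$
is itself a configurable quantity.

## Inference

`fit_dose_response()` samples the posterior by MCMC through JAGS
(rjags), which is asymptotically exact for this model; the model
declaration mirrors the likelihood and priors above, with sampling on
transformed scales ($\log C$, the efficacy ratios) so every draw satisfies
the parameter constraints by construction. The default configuration —
4 chains of 1000 iterations with 500 warm-up, retaining 2000 draws — is
the standard screening configuration for this model family and takes about
a second per matrix. Warm-up is implemented as the sampler's adaptation
phase; each chain starts from an independent prior-drawn initial point and
has its own RNG seed derived from `seed`, so fits are bit-reproducible.

Convergence is *reported, not enforced*: `diagnostics_report()` computes
per-parameter split-$\widehat{R}$ and effective sample size and flags the
fit as converged when all $\widehat{R} < 1.05$ and ESS $\ge 100$. A
non-converged fit returns its draws with a warning; the caller decides. Two
situations deserve attention:

* **Weakly identified matrices** (doses far below the IC50, no response
  plateau) produce genuinely wide and sometimes multimodal posteriors —
  e.g. Einf has mass both near "fully effective, dose range too small" and
  "inactive". This is the model doing its job; chains can be slow to
  traverse the modes, so for uncertainty-critical summaries we recommend
  longer chains (see below).
* The Gibbs-type sampler mixes more slowly per iteration than
  gradient-based samplers on this posterior. The package's own calibration
  studies therefore use 4 chains of 4000 iterations (3000 retained per
  chain after 1500 warm-up); at roughly four seconds per matrix this keeps
  a 50-matrix study under four minutes on one CPU.

## The synthetic-data generator

`simulate_dose_matrix()` draws a ground-truth parameter point (supplied, or
sampled from the prior), evaluates the combination surface on a dose grid,
and adds i.i.d. Gaussian noise to every cell, including the base cell and
the monotherapy slices. Two layouts mirror the public screens: `dream_6x6`
(36 points: 1 base + 2 x 5 monotherapy + 25 grid) and `almanac_15`
(16 points: 1 base + 2 x 3 monotherapy + 9 grid). Defaults chosen once and
held fixed:

* With an explicit truth, dose grids are log-spaced over
  $[C/100,\ 100\,C]$ per drug, which brackets the IC50 and makes the
  matrix informative; passing doses far below $C$ deliberately reproduces
  the unsaturating, efficacy-uncertain regime.
* With a prior-drawn truth, fixed grids $10^{-2}..10^{2}$ (5 points) and
  $10^{-1}..10^{1}$ (3 points) are used: the prior IC50 spans sixteen
  decades, so no finite grid can track it, and calibration studies must
  not condition the design on the estimand anyway.
* Negative simulated responses are **kept** — the Gaussian noise model
  allows them — whereas `read_dose_response()` rejects negative responses
  in real screening files, mirroring the upstream filtering of the public
  datasets. This asymmetry is intentional.

What the generator does *not* emulate: plate and edge effects, correlated
replicates, non-Gaussian noise, enhancement-type (growth-stimulating)
responses. Tests that pass on this generator therefore certify the
inferential machinery under the model's own assumptions — they say nothing
about model misspecification on real screens.

## Prediction and calibration

Held-out evaluation follows the screening protocols: `split_dream()`
leaves out 7 of the 35 non-base points (one per monotherapy slice, so each
single agent keeps a held-out measurement, plus 5 of the 25 grid points);
`split_almanac()` leaves out 3 of 15 with no slice constraint (the slices
are too small); the base point is never held out. Splits are seeded
shuffles, serialisable as index lists.

For a held-out dose $\tilde{x}$, the posterior predictive distribution is
the Monte-Carlo mixture over the $M$ retained draws
$p(\tilde{y} \mid D, \tilde{x}) \approx \frac1M \sum_m
N(\tilde{y};\ \mu(\theta_m, \tilde{x}),\ \sigma_m^2)$ — never a single
Gaussian at the posterior-mean parameters. `evaluate_predictions()` reports

* RMSE of the posterior predictive means,
  $\sqrt{\sum_i (y_i - \hat{y}_i)^2 / N}$;
* the per-point log predictive densities, summarised by their **mean** (the
  per-point convention; the per-point vector is retained so a sum can be
  recovered);
* PIT values $F_M(y_i)$ — the mixture CDF at each observation, computed
  exactly from the mixture rather than by randomised per-draw PIT, which
  is unnecessary for a continuous predictive distribution — and their
  one-sample Kolmogorov-Smirnov uniformity p-value (`stats::ks.test`),
  applied per combination; pooling PIT values across combinations is
  supported as a more powerful aggregate check.

## What the package's own studies compute

The test suite and `scripts/acceptance.R` run a simulation-based
calibration study: 50 `dream_6x6` matrices with truths drawn from the
exact prior used for fitting, split 28/7, refit with 4 x 4000 iteration
chains. Under a correctly implemented sampler, 90% credible intervals for
$\log C_1$, $\log C_2$, $\log\alpha$ and $E_3$ must cover the truth at
90% up to binomial noise, and the pooled K-S rejection rate of the
held-out PIT values at the 5% level must sit at 5% up to binomial noise.
These checks are exact properties of Bayesian inference on well-specified
data, which is what makes them usable as acceptance gates without any
reference dataset. Residual deviation below nominal coverage at finite
chain length is Monte-Carlo error from slowly mixing, multimodal
posteriors (the diagnostics flag exactly those fits), not a property of
the model.

## Numerical choices and edge cases

* Zero doses never enter a logarithm: indicator variables keep the Hill
  fraction at 0 (its limit) on dose-zero cells, in R and in the sampler.
* Combination-surface weights are max-normalised on the log scale;
  overflow would otherwise occur for $H \gtrsim 20$ at extreme dose/IC50
  ratios.
* Quantile summaries of IC50 are computed on the log scale and
  exponentiated (equal to raw-scale quantiles by monotonicity, but the log
  scale is the parameter's natural one and is what the credible intervals
  mean).
* Ties: a draw with $\Delta\mathrm{HSA} = 0$ or $\alpha = 1$ exactly
  counts as non-synergistic (strict inequalities).
* Degenerate datasets (a single dose-zero point) are accepted from the
  constructor with a warning and return the prior, which is the correct
  posterior for an uninformative dataset; file loading is stricter and
  refuses them.
* The train/test contamination guard compares a canonical fingerprint of
  the training data against the one stored in the fit.

## Limitations

Two-drug combinations only; inhibition scale only (responses decreasing
in dose); Gaussian, homoscedastic noise; no replicate correlation or plate
effects; the detailed-balance surface excludes the more general
non-detailed-balance parameterisations. The K-S test at 7 held-out points
has limited power per combination — the calibration study pools its
decisions across matrices for that reason.

## A worked example

```{r example, eval = FALSE}
library(dosebayes)

truth <- list(
  E0 = 100, E1 = 40, E2 = 50, E3 = 5, C1 = 1, C2 = 2,
  H1 = 1.2, H2 = 0.8, alpha = 5, sigma = 2
)
sim <- simulate_dose_matrix("dream_6x6", truth = truth, seed = 1)
split <- split_dream(sim$data, seed = 1)

fit <- fit_dose_response(split$train, seed = 1)
tidy(fit)                        # posterior medians and 95% intervals
synergy(fit)                     # P(synergistic efficacy), P(synergistic potency)
glance(evaluate_predictions(fit, split))  # RMSE, mean log density, K-S p

autoplot(fit)                    # posterior mean surface
autoplot(synergy(fit))           # delta-HSA and log-alpha histograms
```
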