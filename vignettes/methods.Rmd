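---
title: "Borrowing strength across countries in health-state valuation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Borrowing strength across countries in health-state valuation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sf6dvalue)
```

## The problem

Preference-based health measures such as the SF-6D describe health as a
six-digit code — one severity level on each of physical functioning, role
limitation, social functioning, pain, mental health and vitality — giving
18,000 distinct states. A country's *value set* assigns every state a
utility on the scale where full health is 1 and death is 0, estimated from
standard-gamble (SG) interviews in which respondents value a sample of
states. Full-scale valuation studies are expensive; small countries and
LMICs often cannot run one. This package implements a nonparametric
Bayesian model for a single country's SG data and, crucially, a transfer
mechanism that reuses a donor country's fitted posterior as an informative
prior for a target country, so that a small target study borrows strength
from a large existing one.

## Data and preprocessing

Each respondent values several states against full health and the worst
state ("pits", `645655`), and values the pits itself against death. Raw SG
indifference values live on a scale anchored at the pits; chaining through
the respondent's own pits valuation \(P\),

\[ SG_{ADJ} = SG + (1 - SG)\,P, \]

puts them on the death/full-health scale. Pits valuations below \(-1\)
(worse-than-death gradings) are floored at \(-1\) *before* chaining; since
\(SG \in [0,1]\) and \(P \in [-1,1]\), chained values can never leave
\([-1,1]\). `build_dataset()` performs both steps, drops missing values
(complete case), excludes respondents whose pits valuation is unusable
(they cannot be rescaled), and reports the inclusion arithmetic
(`inclusion_report()`); the pits question itself enters the modelling data
like any other state. Whether the \(-1\) floor should also apply to raw
non-pits responses is unresolved in the source descriptions of these
surveys; we implement floor-on-pits, and the choice is isolated in
`truncate_pits_value()` so an alternative rule can be injected.

## The single-country ("crude") model

For respondent \(j\) valuing state \(x_{ij}\),

\[ y_{ij} = 1 - \alpha_j\{1 - u(x_{ij})\} + \epsilon_{ij}, \qquad
   \alpha_j \sim LN(\gamma_0, \tau^2), \quad
   \epsilon_{ij} \sim N(0, v^2). \]

\(u(x)\) is the population utility function; \(\alpha_j\) is a
respondent-specific multiplier on disutility \(1 - u\), log-normal to
capture the right skew typical of valuation data. \(u\) receives a
Gaussian-process prior with mean \(\gamma + \beta^\top (x - 1)\), linear in
the *centred* levels, and covariance \(\sigma^2 c(x, x')\) with the
squared-exponential kernel on levels

\[ c(x, x') = \exp\Big\{-\sum_{d=1}^6 b_d (x_d - x'_d)^2\Big\}. \]

The roughness parameters are fixed, not sampled (inference for them is
notoriously poorly identified in GP models): the default
\(b_d = 2.5/(l_d - 1)^2\) makes the correlation between the extreme levels
of any one dimension \(e^{-2.5} \approx 0.08\) — close to linear, but free
to bend. Centring the levels makes full health contribute only the
intercept, and the exact anchor \(u(\text{full health}) = 1\) is imposed by
*conditioning* the GP prior on that value; without centring, the intercept
would be confounded with the slopes. The reported population mean utility
is \(\bar u(x) = 1 - \bar\alpha\{1 - u(x)\}\) with
\(\bar\alpha = \exp(\gamma_0 + \tau^2/2)\), the log-normal mean, evaluated
per posterior draw.

### Priors, and a necessary departure from the fully flat convention

Variances carry the conventional noninformative densities
\(p(\tau^2) \propto \tau^{-2}\), \(p(v^2) \propto v^{-2}\),
\(p(\sigma^2) \propto \sigma^{-1}\), and the GP mean coefficients are flat.
The multiplier location \(\gamma_0\), however, **cannot** be flat: the
likelihood is exactly invariant under

\[ \alpha_j \to k\,\alpha_j, \qquad 1 - u(x) \to (1 - u(x))/k, \qquad
   \gamma_0 \to \gamma_0 + \log k, \]

and with flat \(\gamma_0\), flat GP mean and \(\sigma^{-1}\), the prior
volume along this ridge grows exponentially in \(|\log k|\): the posterior
is improper. (We verified this directly: a sampler able to traverse the
ridge drifts without bound, and with a \(N(0, s^2)\) prior on \(\gamma_0\)
the posterior location settles at \(-(p+1)s^2\), exactly the rate the
volume argument predicts, where \(p\) is the GP-mean dimension.)
`sf6dvalue` therefore places a proper \(N(0, 0.1^2)\) prior on
\(\gamma_0\) (`prior_gamma0_sd` in `mcmc_config()`). Substantively this
says the population-median multiplier lies within about 20% of 1 — a weak
statement for data already expressed on the anchored utility scale — and
it leaves all likelihood-identified quantities (\(\bar u\), \(\tau^2\),
\(v^2\), fit and prediction) untouched; only the arbitrary split of scale
between \(\alpha\) and \(1-u\) is regularised.

### Sampler

`fit_crude()` runs a Metropolis-within-Gibbs chain:

* the utility vector \(u\) over the valued states is a single
  multivariate-normal block draw (the model is linear-Gaussian in \(u\)
  given the rest);
* each \(\log \alpha_j\) is a random-walk Metropolis update, vectorised
  over respondents;
* \(v^2\) and \(\tau^2\) have inverse-gamma full conditionals; \(\gamma_0\)
  and the GP mean coefficients have normal full conditionals;
* \(\log \sigma^2\) is random-walk Metropolis;
* one extra *joint rescaling* move proposes the
  \((\alpha, 1-u, \gamma_0)\) transformation above. It leaves the
  likelihood and the multiplier prior invariant, so its Hastings ratio is
  just the GP prior ratio times a Jacobian; without it the scale direction
  mixes pathologically slowly.

Proposal scales adapt toward a 20–50% acceptance rate during burn-in and
are frozen afterwards, preserving detailed balance of the retained chain.
Defaults are 10,000 sweeps, 2,000 burn-in, thinning 5. Runs are exactly
reproducible from the seed. Numerical safeguards: GP covariances carry a
`1e-8` diagonal jitter (inflated once, then abort, on Cholesky failure);
values at the \(\pm 1\) instrument bounds are treated as exact
observations (plain normal likelihood, no censoring term); with fewer than
8 distinct states the linear GP mean is unidentified and the fit insists
on `mean_basis = "intercept"`.

## Cross-country transfer

`export_posterior()` turns a fitted donor into a portable bundle: the
posterior mean vector and covariance matrix of the *latent* \(u\) (not
\(\bar u\)) over any states, with full health included exactly. For a
target country, the GP prior becomes

\[ E\{u(x)\} = \sum_k E\{u_k(x)\} + \gamma + \beta^\top x, \qquad
   \mathrm{cov} = \sum_k \mathrm{cov}_k(x, x') + \sigma^2 c(x, x'), \]

summing over donors \(k\): the donor posterior is carried over verbatim,
the sampled offsets \((\gamma, \beta)\) absorb systematic cross-country
preference differences dimension by dimension, and the fresh
\(\sigma^2 c\) layer lets the target surface fluctuate around the donor's.
Estimation is two-stage plug-in — donor bundles are fixed, never
re-estimated — matching the sequential logic of borrowing from "readily
available" existing data. Donor quantities at states the donor never
valued are obtained by GP conditioning inside the donor fit
(`predict_states()`), which is also how either model values any of the
18,000 states. Donors are equally weighted by default; `weights` exists as
an experimental hook because principled weighting of unequal donors is an
open question. The target-country kernel uses the same roughness defaults
as the donor's (the package exposes `roughness` if a different choice is
wanted).

Prediction at new states propagates full conditional *draws* per retained
iteration, so reported standard deviations include GP interpolation
uncertainty; `method = "mean"` switches to conditional means only.

## Synthetic data

No raw SG valuation data from these studies are publicly available, so
`simulation_scenario()` / `sample_true_utilities()` /
`generate_valuations()` generate datasets with *exactly* the model's
structure: a true utility surface drawn from the anchored GP around the
linear mean; a target surface equal to the donor truth plus offsets plus a
fresh GP layer; log-normal multipliers; additive normal noise; balanced
round-robin allocation of states to respondents; completely-at-random
missingness. `canonical_scenario()` reproduces the canonical two-study
layout — 249 donor states × 611 respondents × quota 6 (missingness
148/3666) and 49 target states × 126 respondents × quota 8 (missingness
16/1008) — with a `scale` argument for desk-speed replicates.

Default truth values: utility decrements per level chosen so the pits
state sits near 0.33 and simulated observed means span roughly 0.32–0.95
(the range seen in real SG summaries); \(\sigma^2 = 0.01\) (surface
wiggles of sd 0.1 around linearity); \(\gamma_0 = 0\), \(\tau^2 = 0.04\),
\(v^2 = 0.01\); modest transfer offsets. Generated values are clipped to
\([-1, 1]\) because the instrument cannot produce values outside it; with
the default noise this clips a few percent of observations at states near
full health, a deliberate, reported misspecification (real SG data are
bounded the same way). Recovery and coverage tests disable clipping
(`clip = FALSE`) to test the sampler against the exact generative model.
What the generator does *not* emulate: probability-wheel granularity
(responses are continuous), respondent covariate effects, informative
missingness, and interview-order effects. Passing recovery tests
therefore validate the inference machinery, not the model's adequacy for
any real population.

## Evaluation battery

`rmse()`, `bland_altman()` (differences taken observed − predicted, sample
standard deviation, limits of agreement \(\pm 1.96 s_d\)),
`monotonicity_audit()` (sample states without replacement, pair each with
a uniformly chosen one-level neighbour, count strict reversals of the
dominance order; ties are not violations, so a constant predictor scores
0), `qaly_cost_illustration()` (utility × years, cost / QALYs), and
`compare_models()` which consolidates these per model and emits the
sorted predicted/observed orderings and scatter data behind the usual
figures. The packaged `table1_fixture()` transcribes the published
per-state posterior summary of the two-country case study (the published
table carries 50 states plus full health, one more than its caption
says); `reproduce_table1()` recomputes all the agreement metrics from it
without any fitting.

## Problem sizes used in the test suite

The suite exercises the full pipeline at deliberately scaled-down sizes
chosen to keep replicate studies cheap while leaving each fit enough data
to be informative: hyperparameter coverage uses 50 replicates of a
30-state × 60-respondent study with 2,000 retained draws; offset recovery
20 replicates of a 17-state × 40-respondent target against a noiseless
donor; the precision-gain comparison 20 paired crude/transfer fits on an
8-state target with 12 held-out states. Coverage thresholds are binomial
bands around the nominal 95% (e.g. 0.84 at 50 replicates), fixed from
that calculation rather than from observed results.

## Known limitations

* The scale split between \(\alpha\) and \(1 - u\) is identified only by
  the \(\gamma_0\) prior; \(\gamma_0\) and the latent \(u\) level should
  not be over-interpreted individually. \(\bar u\), the quantity a value
  set reports, is identified.
* Two-stage plug-in ignores donor-posterior non-normality and any feedback
  from target to donor.
* Boundary observations are modelled without censoring; with very noisy
  data near full health this biases \(v^2\) and \(\tau^2\) slightly
  downward (visible when fitting clipped synthetic data).
* Non-default donor weights are untested beyond the sum-consistency
  checks; treat them as experimental.
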