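---
title: "Heterogeneity priors for sparse-event meta-analysis: model, engine and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneity priors for sparse-event meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Meta-analyses in rare diseases typically pool a handful of small
randomized trials with a binary outcome.  With per-arm sample sizes of
5–50 and event rates of 5–30%, zero-event arms are the rule rather than
the exception.  The classical normal–normal random-effects model then
needs continuity corrections that distort both point and interval
estimates, and with so few trials the between-study standard deviation
tau is barely identified: whatever prior is placed on tau leaks directly
into the posterior of the overall treatment effect.

`bnhm` provides the machinery to study and use this setting properly:
an arm-level binomial likelihood (no corrections), a library of twelve
heterogeneity priors spanning the shapes proposed in the literature, a
self-contained MCMC engine, a trial simulator, and a coverage/bias
evaluation pipeline for comparing priors.

## The model

For trials \(i = 1, \dots, k\) with arms \(j \in \{T, C\}\):

\[
r_{ij} \sim \mathrm{Binomial}(\pi_{ij}, n_{ij}), \qquad
\mathrm{logit}(\pi_{iT}) = \mu_i + \tfrac12 \delta_i, \qquad
\mathrm{logit}(\pi_{iC}) = \mu_i - \tfrac12 \delta_i,
\]

with trial-specific log odds ratios \(\delta_i \sim N(\delta, \tau^2)\).
The overall effect gets a weakly diffuse prior
\(\delta \sim N(0, 100)\) — its 95% prior range is \((-19.6, 19.6)\) on
the logOR scale, wide enough to be non-informative for any plausible
treatment effect while avoiding the numerical instability of
variance-1000 priors.  Baselines are exchangeable,
\(\mu_i \sim N(\mu_0, 100)\).

Centering the \(\mu_i\) "around their own mean" is self-referential as a
generative statement, so the package treats \(\mu_0\) as a hyperparameter
with a vague \(N(0, 10^6)\) hyperprior and a conjugate Gibbs update.
This reproduces the intended behaviour — the baseline centre is learned
from the data — without a circular graph.  It is the one genuinely open
design choice in the model; with \(k \le 6\) small trials the posterior
of \(\delta\) is insensitive to hyperprior variances beyond ~\(10^2\)
(the Gibbs update shrinks by \(k/100\) versus \(1/\sigma_0^2\)).

## The heterogeneity prior library

`tau_prior()` builds any of twelve priors, each stated for a transform
\(g(\tau)\):

| id | \(g(\tau)\) | distribution | character |
|----|-------------|--------------|-----------|
| AG / ag | \(1/\tau^2\) | Gamma(0.001, 0.001) / Gamma(0.1, 0.1) | mass near 0, extreme tail |
| AU / du | \(\log \tau^2\) | Uniform(−10, 10) / Uniform(−10, 1.386) | mass near 0, long tail |
| B / b | \(\tau^2\) | Uniform(0, 1000) / Uniform(0, 4) | mass at large \(\tau\) |
| C / c | \(\tau\) | Uniform(0, 100) / Uniform(0, 2) | flat on \(\tau\) |
| DN / dn | \(\tau\) | Half-normal(0, 100) / Half-normal(0, 1) | bounded plausible range |
| E | \(s_0/(s_0+\tau)\) | Uniform(0, 1) | empirical (DuMouchel) |
| e | \(\tau^2\) | Half-normal(0, \(\Phi^{-1}(0.75)/s_0\)) | empirical |

Conventions that matter and are verified by the test suite:

* The half-normal's second argument is a **variance** (BUGS-style), so
  DN has SD 10 on the \(\tau\) scale and median
  \(10 \times \Phi^{-1}(0.75) = 6.745\); parameterizing by SD would give
  67.4 and contradict the published quantiles of this prior family.
* The gammas are shape/rate.
* \(s_0 = \sqrt{k / \sum_i s_i^{-2}}\), the square root of the harmonic
  mean of the within-study logOR variances \(s_i^2\), so \(s_0\) has the
  units of \(\tau\) and the DuMouchel ratio is dimensionless.  The
  \(s_i^2\) are computed with a 0.5 continuity correction added to all
  four cells of any trial containing a zero cell — this correction
  feeds **only** the empirical prior scale, never the likelihood.
* Prior e's scale \(\Phi[0.75]/s_0\) is read as the standard-normal 75%
  quantile (0.6745) divided by \(s_0\), used as the variance of the
  half-normal on \(\tau^2\).  The notation is ambiguous (it could mean
  the CDF value); this reading is documented rather than asserted
  against published numbers.
* The gamma-precision priors put substantial \(\tau\)-mass beyond the
  double-precision range (for AG, >20% of the mass lies above
  \(e^{745}\)); published quantile tables for those two rows are
  internally inconsistent, so the package computes its own quantiles
  for them and the tests do not pin them to printed values.

`prior_density()`, `prior_cdf()`, `prior_quantile()` and
`prior_sample()` all operate on the \(\tau\) scale (the density includes
the Jacobian of \(g\)); sampling happens on each prior's native scale so
no clipping enters inference.

## The MCMC engine

`bnhm()` runs an adaptive Metropolis-within-Gibbs sampler (C++ core):

* \(\delta\) and \(\mu_0\) have conjugate normal Gibbs updates;
* each \(\mu_i\) and \(\delta_i\) a scalar random-walk Metropolis update;
* \(\tau\) is updated through an unconstrained transform of its native
  scale — log precision for AG/ag, logit of the bounded uniform for
  AU/du/B/b/C/c, \(\log \tau\) or \(\log \tau^2\) for the half-normals,
  logit of the shrinkage ratio for E — with the reparameterization
  Jacobian in the target.  This avoids hand-written Jacobians on the
  \(\tau\) scale and keeps bounded supports exact.

Proposal scales adapt in batches of 50 iterations toward 44% acceptance
during burn-in only; after burn-in they are frozen, so the post-burn-in
chain satisfies detailed balance.  Initialization: \(\mu_i\) at pooled
empirical logits with a 0.5 correction, \(\delta = \delta_i = 0\),
\(\tau\) at its prior median capped into \([0.01, 5]\) — a finite
starting density for every prior, including double-zero datasets.

Defaults (3 chains of 30 000, burn-in 4 500, thin 3) are sized for
simulation replicates.  Case-study analyses under the heavy-tailed AU
prior mix slowly in \(\tau\) and should run much longer; the packaged
case-study script uses 3 chains of 5 million with thinning 100, which
brings the Monte-Carlo SE of the posterior median of \(\delta\) below
0.02 in under two minutes per fit.

Gibbs steps fall back gracefully for degenerate states: \(\tau^2\) is
floored at 1e−300 in the conditional precision of \(\delta\), and the
normal log-density floors \(\tau\) at 1e−150, so gamma-precision priors
that wander to extremely small \(\tau\) do not produce NaNs.

Every fit reports split-\(\widehat{R}\) and bulk ESS (Geyer
initial-monotone autocorrelation sums over split chains) for \(\delta\)
and \(\tau\); a fit with \(\widehat{R} > 1.05\) or ESS < 400 is
returned, flagged and warned about — never silently discarded, and the
evaluation pipeline counts rather than drops such replicates, because
conditioning on convergence would bias coverage estimates.

## Checking the engine

The test suite pins the sampler to independent references:

* at \(k = 1\) with \(\tau\) fixed (the `"fixed"` prior) the posterior
  mean and SD of \(\delta\) match 2-D brute-force quadrature over the
  trial's random effect and baseline within 3 Monte-Carlo SEs;
* with the likelihood switched off (`include_likelihood = FALSE`) the
  sampler reproduces each heterogeneity prior's quantiles — a direct
  check of every transform/Jacobian pair;
* a JAGS fit of the identical model (through the rjags package, in
  Suggests) agrees on the case-study posterior median;
* swapping treatment and control negates the posterior of \(\delta\),
  and a fixed seed reproduces draws bit-identically.

## The simulator

`ma_scenario()`/`simulate_meta()` implement arm-level heterogeneity:
equal per-arm sizes drawn uniformly on an integer range, then

\[
\theta_{iC} \sim N(\mathrm{logit}(\pi_c), (\tau/2)^2), \qquad
\theta_{iT} \sim N(\mathrm{logit}(\pi_c) + \delta, (\tau/2)^2)
\]

independently, and binomial events from the back-transformed
probabilities.  Because the arms are independent, the implied SD of the
trial-level logOR \(\theta_{iT} - \theta_{iC}\) is \(\tau/\sqrt 2\),
not \(\tau\).  The mechanism is implemented exactly as stated — the
per-arm SD is \(\tau/2\) — and the tests assert the \(\tau/\sqrt 2\)
consequence explicitly rather than "correcting" it; analyses comparing
nominal \(\tau\) to posterior \(\tau\) should keep this factor in mind.

Zero-event arms and all-zero datasets are retained: they are the point
of the sparse-event setting, and the binomial-normal posterior remains
proper for them.

Replicate r of a scenario uses an RNG substream derived from the
scenario seed and r (a fixed linear-congruential hash), so any replicate
can be regenerated independently and runs are bit-reproducible
end-to-end.  The full factor grid (`scenario_grid("paper_full_factors")`)
crosses \(k \in \{2,4,6\}\), per-arm n uniform on [5,10] or [40,50],
\(\pi_c \in \{0.05, 0.1, 0.3\}\), \(\tau \in \{0.01, 0.5, 1\}\) and
\(\delta \in \{0, 0.5, 3\}\): 162 cells.  `"desk_small"` is a 12-cell
subset for a single workstation: \(k \in \{2, 6\}\) crossed with both
size ranges and three \((\pi_c, \tau, \delta)\) profiles —
(0.05, 1, 3) the sparse stress case, (0.1, 0.5, 0) an intermediate null,
(0.3, 0.01, 0.5) the information-rich near-homogeneous case — capped at
200 replicates.

## The evaluation pipeline

`eval_priors()` reports, per scenario × prior: the average posterior
median of \(\delta\), 95% CrI coverage of the true \(\delta\), the MSE
of the posterior median, and the average posterior median of \(\tau\),
each with a Monte-Carlo SE (binomial formula for coverage, sample
SD/\(\sqrt{\text{reps}}\) for means).  All intervals are equal-tailed
2.5–97.5% quantile intervals (the BUGS-style summary), not HPD.
`comparison_table()` flattens results to tidy long format so any
averaging over scenario subsets is explicit in user code.

At desk scale the package uses 200 replicates per scenario (MC-SE of a
95% coverage estimate: 1.5 percentage points) and the 30k/4.5k/thin-3
chain settings per replicate; property-style tests use 10k-iteration
chains, which leave the coverage estimator's bias well below its MC-SE
in the scenarios tested.

One consequence of the literal per-arm mechanism deserves emphasis when
judging \(\tau\) estimates: the effective SD of the trial-level logOR is
\(\tau/\sqrt 2 \approx 0.71\) at nominal \(\tau = 1\), which happens to
sit at the dn prior's own median (0.67).  Raw "bias at \(\tau = 1\)"
therefore flatters dn for a coincidental reason.  The informative
comparison — and the one the tests assert — is *discrimination*: between
\(\tau = 0.01\) and \(\tau = 1\) the AU posterior median of \(\tau\)
moves by ~0.44 while dn's moves by ~0.33 and stays near its prior mass
whatever the truth, and at \(\tau = 0.01\) AU's estimate (~0.08) is far
closer to the truth than dn's (~0.34).

What desk-scale simulations show — and what they do not: with 200
replicates the qualitative ordering of priors (e.g. the heavy
overestimation of \(\delta\) under B/C/DN in sparse cells, the robust
coverage of AU) is reproducible, but two-decimal coverage values and
the full 1994-scenario surface are not; nothing in the package asserts
those.  The simulator also idealizes real meta-analyses: no publication
bias, no unequal arm sizes, exact exchangeability of baselines, and
normal random effects — passing tests say nothing about robustness to
those violations.

## Case studies

Two transcribed datasets ship with the package: `mmn_trials()` (3
trials, intravenous immunoglobulin vs placebo in multifocal motor
neuropathy — 36 patients, one double-zero trial) and `gbs_trials()` (4
trials, immunoglobulin vs plasma exchange in Guillain-Barre syndrome —
treatment discontinuation, two zero-event treatment arms).
`prior_sensitivity()` runs all twelve priors on a dataset and tabulates
the posterior medians and CrIs of \(\delta\) and \(\tau\): on these
data the posterior median logOR moves by about one unit depending only
on the \(\tau\) prior, the sensitivity the package exists to expose.

The beneficial-direction probability reported by `prob_direction()` is
the posterior mass on the side of zero containing the posterior median;
for the discontinuation outcome (fewer events favour immunoglobulin)
that side is \(\delta < 0\), so the convention avoids hard-coding which
sign is "good" per outcome.

## Known limitations

* Equal random-effect variance is assumed for both arms' logits;
  unequal-variance variants are not implemented.
* Only the log odds ratio scale is supported (no risk ratio or risk
  difference), and only normal random effects.
* The AG prior mixes poorly by construction (its mass sits at
  astronomically large \(\tau\)); its diagnostics routinely flag short
  runs, which is a finding about the prior, not a sampler defect.
* MC-SEs for posterior medians use the normal-approximation inflation
  \(\sqrt{\pi/2}\,\mathrm{sd}/\sqrt{\mathrm{ESS}}\); for very
  heavy-tailed posteriors they are approximate.
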