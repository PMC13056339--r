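---
title: "Counterfactual causal selection with plural causes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual causal selection with plural causes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pluralcause)
```

This vignette is the package's account of its science: the counterfactual
models it implements, the conventions it adopts where the underlying theory
leaves choices open, and what its tests do and do not establish.

## The modeling frame

All scoring happens in a *flat* structural causal model: a set of
independent binary exogenous variables, each with a marginal prior
probability ("normality"), and one Boolean outcome rule. There are no
intermediate nodes and no dependence between variables — in the urn games
the package targets, every draw is an independent Bernoulli event and the
outcome is a deterministic function of the draws. Rules are written in a
small grammar (`&`, `|`, `!`, parentheses, and the threshold form
`count(v1,...,vk)>=m`); the threshold form is first-class syntax so that
"win with two or more colored balls" stays readable, and it evaluates
identically to its expanded disjunction.

A *candidate cause* is a non-empty conjunction of literals — a singular
cause names one variable's value, a plural cause several. The package
treats a plural holistically: the conjunction is one compound binary
variable whose counterfactual profile is scored wholesale, never an
aggregate of its conjuncts' scores. The empty conjunction is rejected:
the trivially true event is never a candidate for selection.

## Counterfactual sampling and stability

Counterfactual worlds are sampled one variable at a time. With probability
`s` — the **stability** parameter, a probability in [0, 1] — a variable
keeps its actual value; with probability `1 - s` it is resampled from its
prior. The package collapses the two stages into a single per-variable
mixture propensity

```
P(value) = s * 1[value = actual] + (1 - s) * (prior if value = 1 else 1 - prior),
```

which is distributionally identical and makes exact enumeration possible:
`enumerate_distribution()` tabulates all `2^n` worlds with their propensity
products (guarded at n = 20). Exact enumeration is the default scoring path
and the oracle against which the Monte-Carlo path (`sample_worlds()`,
default `1e5` draws) is tested. At `s = 0` the distribution is the product
of priors regardless of the actual world; at `s = 1` it is a point mass on
the actual world. Seeds are mandatory arguments on every stochastic path
and never global state; sampling saves and restores the caller's RNG
state.

One question the two-step procedure leaves open is whether Monte-Carlo
scores for different candidate causes should share one sample. The package
computes all candidates of a round from one shared exact distribution, and
its Monte-Carlo mode draws one sample per call; the tests that compare the
two use an independently seeded sample per cause so that each comparison
is an independent 3-standard-error event.

## The two scoring models

**CESM.** The causal responsibility of cause `V` for outcome `O` is the
Pearson correlation between the cause indicator and the outcome across the
counterfactual distribution. In these flat binary structures the fuller
effect-size machinery of the CESM literature reduces to this correlation,
so only the correlation form is implemented. When either variable has zero
variance (at `s = 1`, or when a cause or the outcome is constant across
worlds) the correlation is undefined; the score is defined as 0, encoding
"no counterfactual dependence". Scores live in [-1, 1].

**NSM.** Two conditional probabilities are combined:

- *Necessity* — among worlds where the cause fails to hold, the
  probability that the outcome differs from its actual value. In the
  default `fixed_at_actual` mode the off-candidate variables are pinned at
  their actual values, so only the cause's own variables vary over the
  complement of the cause; in the `resampled` mode they follow their
  sampling propensities too. The default follows the worked
  three-dessert example this package reproduces (the cheese stays fixed
  even at `s = 0`); the resampled variant, closer to the original NSM
  literature, is available behind the `off_candidate_mode` switch for
  sensitivity analysis, because fitted parameters alone cannot
  disambiguate the two readings.
- *Sufficiency* — condition on worlds where both the cause and the outcome
  differ from their actual values, intervene by forcing the cause's
  literals, and ask how often the outcome is restored.

The combined score is the convex combination weighted by the cause's prior,
`prior * sufficiency + (1 - prior) * necessity`. A conjunction is never
more probable than its conjuncts, so plural causes automatically lean
harder on necessity. Zero-mass conditioning regions return 0 (with a
message under `options(pluralcause.verbose = TRUE)`) rather than erroring,
which keeps grid searches total over `s`, including the `s = 1` boundary.
A consequence worth knowing: in `fixed_at_actual` mode the necessity of a
singleton cause is always exactly 0 or 1 — flipping one variable with
everything else pinned is deterministic.

## Losing rounds: the homogeneous-negation mixture

When the outcome to be explained is a *loss*, the candidate causes are
negative literals ("drew a white ball") and the scored outcome is LOSS.
The classical reading takes LOSS to be the negation of the winning rule.
The non-classical reading mirrors how natural language negates plurals
homogeneously: the *strong* loss rule is the conjunction of `!X` over
exactly those variables whose actual value is 0 — the most homogeneous
negation that does not contradict the established facts of the round (a
variable that was actually present cannot be blamed for being absent, so
it is excluded).

`augment_with_interpretation()` mixes the two readings with weight `w`: an
extra binary variable `I` with prior `w` decides, in each counterfactual
world, which reading applies; worlds that are not losses under the selected
reading count as wins. Two interpretation choices are deliberate:

- `I` is **never anchored** by `s`. The interpretation decision is made
  afresh in every simulated world — it is a property of the simulation,
  not a stable fact of the actual round.
- `I` is likewise marginalized, never pinned, in the NSM's
  `fixed_at_actual` conditioning, for the same reason.

At `w = 0` every prediction equals the classical-negation model to within
1e-12 (tested), and the augmented distribution marginalizes back to the
base distribution when `I` is summed out. The strong-rule construction
generalizes the two concrete losing rounds of the four-urn experiment
(all-absent, giving the four-way conjunction of negations, and
three-absent, dropping the present urn) by the stated principle rather
than by special cases.

## Fitting conventions

`fit_causal_model()` fits by grid search, maximizing the Gaussian
likelihood of per-question mean ratings around scaled model predictions.
The conventions, each of which the underlying theory leaves open:

- **Scale reconciliation.** Observed means (1–9 Likert) are affinely
  rescaled to [0, 1] via `(m - 1) / 8` before the likelihood; predictions
  already live in [0, 1] (CESM scores can be negative; see clipping
  below). This puts the two on a common scale without extra free
  parameters.
- **Scaling exponent γ.** Predictions enter the likelihood as
  `pmax(raw, 0)^gamma`, `gamma > 0`. γ absorbs uniform over/undershoot
  without changing predicted orderings. Negative raw scores are clipped to
  0 first — a power of a negative base is undefined — and clipping is
  logged in verbose mode.
- **σ profiled out.** At each grid point the residual standard deviation
  is set to its closed-form maximum-likelihood value (the RMS residual)
  instead of being gridded.
- **Grids.** Defaults: `s` and `w` over `seq(0, 1, 0.01)`, γ over
  `seq(0.05, 3, 0.05)`. `w` is searched only when the data contain losing
  rounds; a length-1 `w_grid` fixes `w` without counting it as a fitted
  parameter, which is how the nested "no-w" model is expressed.
- **Ties.** Broken toward smaller `s`, then smaller `w`, then smaller γ
  (the first lexicographic maximum wins).
- **Information criteria.** `AIC = 2k - 2 logL`,
  `BIC = k log(Q) - 2 logL`, with `Q` the number of questions and `k`
  counting the searched parameters plus σ (3 for positive-only fits, 4
  with `w`; 2 for the constant baseline). This is a question-mean
  likelihood: participant-level mixed-effects criteria are a different
  quantity and out of scope here.
- **Baselines.** The constant baseline predicts `0.5^gamma` for every
  question (the mid-scale value; the underlying choice of constant is
  otherwise arbitrary) and its correlation with the means is reported as 0
  by convention. The linear-combination baseline predicts each pair as the
  arithmetic mean of its two singular means on the raw 1–9 scale,
  rescaled only afterward.

For grid-search speed, winning-round predictions (which do not depend on
`w`) are cached per `s`, and all causes of a round are scored from one
precomputed world table; a full default-grid (s, w, γ) fit of the four-urn
losing rounds takes a few seconds on one core.

## The synthetic participant generator

`generate_ratings()` emulates the statistical structure the fitting stage
assumes: participant i's latent response to question q is
`scaled prediction + b_i + e_iq`, with mean-zero normal participant
intercepts `b_i` (response-style/scale-use differences) and mean-zero
normal noise `e_iq`, both in latent [0, 1] units, mapped to 1–9 by
`round(1 + 8 * latent)` and clipped. Defaults, chosen once as realistic
for this kind of Likert data: `noise_sd = 0.12` (about one rating point of
trial noise) and `intercept_sd = 0.05` (just under half a rating point of
stable between-participant offset).

What the generator deliberately does **not** emulate: order-of-presentation
effects (real singular ratings drop when asked after plurals),
per-participant heterogeneity in `s` or `w`, and any ordered-categorical
response process — discretization is plain rounding, because the fitting
stage consumes means, for which rounding bias is small and uniform. Two
consequences matter for interpreting recovery results. First, rounding and
clipping put a small floor under recovery error that does not shrink with
more participants. Second, when γ compresses predictions toward the top of
the scale (e.g. γ ≈ 0.26), ceiling clipping biases question means slightly
downward, which can displace the fitted `s` by a few grid steps even with
many participants. The package's recovery checks therefore use the
moderate sample sizes a behavioral study would (300 participants, 20
replications) and ask for median recovery error within 0.1 — they show
the fitting machinery identifies its parameters under the generator's
assumptions, not that real participants satisfy those assumptions.

## Problem sizes and numerical tolerances in the test suite

Exact scores are compared against an independent brute-force truth-table
oracle (world enumeration via `expand.grid`, weighted correlation via
`stats::cov.wt`) at 1e-12 on every question of both built-in experiments,
for `s` in {0, 0.3, 0.7}, and against the hand-written mixture-rule oracle
for the augmented loss model. Monte-Carlo agreement is tested at `1e5`
draws within 3 standard errors, with the SE computed by the delta method
from the exact distribution. Recovery studies run 20 replications of 300
participants (the ladder test uses 30/300/3000 with 6 replications).
These sizes were chosen so the whole suite runs in a few minutes on one
core while keeping every check at its stated tolerance.

## Known limitations

- Variables are strictly binary and independent; no intermediate causal
  nodes, no multi-valued variables, no disjunctive candidate causes.
- Exact enumeration is capped at 20 variables; beyond that only the
  Monte-Carlo path would apply (and is not the tested default).
- The likelihood is over question means; conclusions about
  participant-level variance components are outside the model.
- The four-urn experiment's default question sets are the exhaustive
  conjunctions of sizes 1–3 of the queried literals. Published uses of
  this paradigm exclude some "redundant" plurals without an explicit
  rule, so the question lists are configurable per round.
- The homogeneity mixture is bivalent: a world is a loss under one reading
  or the other. Truth-value-gap (trivalent) semantics for plural negation
  are not modeled.
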