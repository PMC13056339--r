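# pluralcause

Counterfactual models of causal selection for singular and **plural
(conjunctive) causes**, in R.

When several events jointly bring about an outcome, people do not only rank
the individual events as causes ("the player won *because he drew a colored
ball from urn B*") — they also evaluate conjunctions of events as causes in
their own right ("… *because he drew colored balls from urns A and B*").
`pluralcause` implements the two leading counterfactual models of causal
selection, extended holistically to such plural causes, for flat structural
causal models with independent binary variables:

- **CESM** (Counterfactual Effect Size Model): the causal responsibility of
  a (possibly compound) binary event *V* for outcome *O* is the Pearson
  correlation ρ(V, O) across counterfactual worlds.
- **NSM** (Necessity–Sufficiency Model): a prior-weighted convex
  combination
  `score = P(V) · sufficiency + (1 − P(V)) · necessity`,
  where *necessity* is the probability that removing *V* removes *O* and
  *sufficiency* the probability that adding *V* produces *O*.

Counterfactual worlds are sampled per variable: with probability *s* (the
**stability** parameter) a variable keeps its actual value, otherwise it is
resampled from its prior — so abnormal (low-prior) events are switched off
more often, which is how normality enters causal judgment. The package
enumerates this distribution exactly (and can sample it Monte-Carlo), scores
singular and plural candidate causes, and fits (*s*, *w*, γ) to mean Likert
ratings by grid-search maximum likelihood.

For **losing** (negative) outcomes the package also implements a
non-classical reading of the losing conditions inspired by how natural
language negates plurals homogeneously ("the boys didn't do their homework"
= *none* did): with probability **w** a counterfactual world's loss is
evaluated by the strong rule that conjoins the negations of all
actually-absent events, otherwise by the classical negation of the winning
rule. At `w = 0` this reduces exactly to classical negation.

The built-in fixtures are two urn-game experiments: three urns with
colored-ball probabilities 0.05 / 0.5 / 0.95 and the threshold rule "win
with ≥ 2 colored balls", and four urns with probabilities 0.7 / 0.1 / 0.2 /
0.9 and the rule `WIN ≔ (A∧B) ∨ (C∧D)` queried over four rounds
(overdetermined/triple, positive/negative).

Intended users: computational cognitive scientists modeling causal-judgment
data, and anyone needing exact counterfactual scoring of conjunctive causes
in small Boolean causal models.

## Worked example

The running example: three dishes — Gouda cheese (P = 0.5), chocolate cake
(P = 0.8), blueberry pie (P = 0.1) — and a stomachache iff two or more are
eaten. All three were eaten. How good a cause of the stomachache is the
plural "cake and pie"?

```r
library(pluralcause)
dessert <- causal_scenario(c(G = 0.5, C = 0.8, B = 0.1),
                           "count(G,C,B)>=2", "three desserts")
nsm_score(dessert, c(G = 1, C = 1, B = 1), "C&B", s = 0)
#> NSM score for B&C (s = 0, fixed_at_actual)
#>   necessity   = 0.1957
#>   sufficiency = 1.0000
#>   prior       = 0.0800
#>   combined    = 0.2600
```

Reading the numbers: with the cheese held fixed, only the cake-and-pie-free
worlds (mass 0.18 of the 0.92 cause-absent region) avoid the stomachache,
so necessity is 0.18/0.92 ≈ 0.20; forcing cake and pie always yields two
desserts, so sufficiency is 1; the plural's prior 0.8 × 0.1 = 0.08 weights
the two into 0.08 · 1 + 0.92 · 0.1957 = 0.26.

Model predictions for the three-urn experiment, at the stability typical of
fits to human ratings (s = 0.89): the intermediate∧high pair is the
strongest plural — winning usually happens through those two urns — even
though the singular *low* outranks *high*:

```r
prediction_table(experiment1(), "cesm", s = 0.89)[, c("cause", "score")]
#>                   cause score
#> 1                   low 0.227
#> 2          intermediate 0.307
#> 3                  high 0.136
#> 4      intermediate&low 0.191
#> 5              high&low 0.232
#> 6     high&intermediate 0.321
#> 7 high&intermediate&low 0.187
```

End to end: simulate 300 participants' 1–9 ratings from the model and
recover the generating parameters by grid search:

```r
r <- generate_ratings(experiment1(), "cesm", s = 0.89, gamma = 0.26,
                      n_participants = 300, seed = 7)
fit_causal_model(r, experiment1(), "cesm")
#> Causal-selection model fit: cesm (7 questions)
#>   s = 0.9, gamma = 0.25, sigma = 0.004973
#>   logLik = 27.19, AIC = -48.39, BIC = -48.55, cor = 0.995
```

The fitted object supports `coef`, `summary`, `predict`, `residuals`,
`logLik`, `AIC`/`BIC`, and `plot`; `compare_models()` tabulates fits, and
`constant_baseline_fit()` / `linear_combination_baseline()` provide the
reference models.

A thin command-line wrapper over these functions (subcommands `predict`,
`fit`, `simulate`, `oracle`) ships in `inst/scripts/pluralcause.R`.

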