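Package: pluralcause
Title: Counterfactual Causal-Selection Models for Singular and Plural Causes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Counterfactual models of causal-selection judgments over flat
    structural causal models with independent binary variables. Implements
    stability-anchored counterfactual sampling and exact enumeration, the
    Counterfactual Effect Size Model (CESM) and the Necessity-Sufficiency
    Model (NSM) generalized to plural (conjunctive) causes, a non-classical
    "homogeneous" negation model for losing outcomes mixed with classical
    negation by a weight w, grid-search maximum-likelihood fitting of
    (s, w, gamma) to per-question mean Likert ratings, urn-game experiment
    fixtures, and a synthetic-participant rating generator for parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
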