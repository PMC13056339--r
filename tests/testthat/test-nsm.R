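test_that("the three-dessert worked example is reproduced exactly", {
  dessert <- dessert_scenario()
  nec <- necessity(dessert, dessert_actual, "C&B", s = 0)
  expect_equal(nec, 0.18 / 0.92, tolerance = 1e-12)
  suf <- sufficiency(dessert, dessert_actual, "C&B", s = 0)
  expect_equal(suf, 1.0, tolerance = 1e-12)
  ns <- nsm_score(dessert, dessert_actual, "C&B", s = 0)
  expect_equal(ns$prior, 0.08, tolerance = 1e-12)
  expect_equal(ns$combined, 0.26, tolerance = 1e-12)
  ## the region masses behind the two normalizations
  expect_equal(0.72 + 0.02 + 0.18, 0.92)  # cake-only + pie-only + neither
  absent_mass <- 1 - cause_prior("C&B", dessert)
  expect_equal(absent_mass, 0.92, tolerance = 1e-12)
  ## sufficiency conditioning mass: cause absent & no stomachache at priors
  w <- oracle_worlds(c("G", "C", "B"))
  p <- oracle_probs(w, c(G = 0.5, C = 0.8, B = 0.1))
  cond <- oracle_indicator(w, c(C = 1, B = 1)) == 0 &
    apply(w, 1, dessert_rule) == 0
  expect_equal(sum(p[cond]), 0.55, tolerance = 1e-12)
})

test_that("necessity is zero for same-disjunct plurals in overdetermined wins", {
  e2 <- experiment2()
  actual <- e2$rounds$overdetermined_positive$actual
  for (s in c(0, 0.3, 0.9)) {
    expect_equal(necessity(e2$scenario, actual, "A&B", s = s), 0,
                 label = paste("s =", s))
  }
  ## Exp 1: flipping one colored ball of three still wins
  e1 <- experiment1()
  expect_equal(necessity(e1$scenario, e1$rounds$win$actual, "low", s = 0), 0)
})

test_that("NSM components match the brute-force oracle on both experiments", {
  e2 <- experiment2()
  actual <- e2$rounds$overdetermined_positive$actual
  for (s in c(0, 0.3, 0.7)) {
    for (cs in c("A", "D", "A&C", "B&D", "A&B&C")) {
      lit <- as_cause_literals(cs)
      expect_equal(necessity(e2$scenario, actual, cs, s = s),
                   oracle_necessity(exp2_priors, actual, s, exp2_rule, lit),
                   tolerance = 1e-12, label = paste("nec", cs, s))
      expect_equal(sufficiency(e2$scenario, actual, cs, s = s),
                   oracle_sufficiency(exp2_priors, actual, s, exp2_rule, lit),
                   tolerance = 1e-12, label = paste("suf", cs, s))
    }
  }
  ## forcing the crossing pair A&C almost always produces a win
  expect_gt(sufficiency(e2$scenario, actual, "A&C", s = 0), 0.85)
})

test_that("trivially sufficient causes and weight collapse behave correctly", {
  ab <- causal_scenario(c(A = 0.5, B = 0.5), "A&B")
  expect_equal(sufficiency(ab, c(A = 1, B = 1), "A&B", s = 0), 1.0)
  dessert <- dessert_scenario()
  expect_equal(sufficiency(dessert, dessert_actual, "C&B", s = 0), 1.0)
  ## prior 0 => combined = necessity; prior 1 => combined = sufficiency
  sc0 <- causal_scenario(c(A = 1, B = 0.5), "A|B")
  ns0 <- nsm_score(sc0, c(A = 0, B = 1), "!A", s = 0)  # prior of !A is 0
  expect_equal(ns0$combined, ns0$necessity)
  sc1 <- causal_scenario(c(A = 1, B = 0.5), "A|B")
  ns1 <- nsm_score(sc1, c(A = 1, B = 1), "A", s = 0)   # prior of A is 1
  expect_equal(ns1$combined, ns1$sufficiency)
  sc2 <- causal_scenario(c(A = 0.5, B = 1), "A&B")
  ns2 <- nsm_score(sc2, c(A = 1, B = 1), "B&A", s = 0.2)
  pri <- cause_prior("A&B", sc2)
  expect_equal(ns2$combined, pri * ns2$sufficiency + (1 - pri) * ns2$necessity)
})

test_that("NSM scores are probabilities and the combination is convex", {
  e2 <- experiment2()
  for (r in names(e2$rounds)[1:2]) {
    tab <- prediction_table(e2, "nsm", s = 0.37)
    expect_true(all(tab$necessity >= 0 & tab$necessity <= 1))
    expect_true(all(tab$sufficiency >= 0 & tab$sufficiency <= 1))
    expect_true(all(tab$score >= pmin(tab$necessity, tab$sufficiency) - 1e-12))
    expect_true(all(tab$score <= pmax(tab$necessity, tab$sufficiency) + 1e-12))
  }
})

test_that("fixed-at-actual necessity of a singleton is deterministic (0 or 1)", {
  e2 <- experiment2()
  dessert <- dessert_scenario()
  cases <- list(
    list(sc = e2$scenario, a = e2$rounds$overdetermined_positive$actual,
         qs = c("A", "B", "C", "D")),
    list(sc = e2$scenario, a = e2$rounds$triple_positive$actual,
         qs = c("A", "B", "D")),
    list(sc = dessert, a = dessert_actual, qs = c("G", "C", "B")))
  for (case in cases) {
    for (q in case$qs) {
      for (s in c(0, 0.5)) {
        nec <- necessity(case$sc, case$a, q, s = s)
        expect_true(nec %in% c(0, 1), label = paste(q, "s =", s))
      }
    }
  }
})

test_that("resampled mode marginalizes off-candidate variables", {
  dessert <- dessert_scenario()
  lit <- c(C = 1, B = 1)
  for (s in c(0, 0.4)) {
    expect_equal(necessity(dessert, dessert_actual, "C&B", s = s,
                           off_candidate_mode = "resampled"),
                 oracle_necessity(c(G = 0.5, C = 0.8, B = 0.1),
                                  dessert_actual, s, dessert_rule, lit,
                                  resample_off = TRUE),
                 tolerance = 1e-12)
  }
  ## at s = 0 resampling the cheese often removes it too, so dropping
  ## cake-and-pie flips the outcome more often than with cheese fixed:
  ## (0.36 + 0.01 + 0.18) / 0.92 against 0.18 / 0.92
  expect_equal(necessity(dessert, dessert_actual, "C&B", s = 0,
                         off_candidate_mode = "resampled"),
               0.55 / 0.92, tolerance = 1e-12)
  expect_gt(necessity(dessert, dessert_actual, "C&B", s = 0,
                      off_candidate_mode = "resampled"),
            necessity(dessert, dessert_actual, "C&B", s = 0))
})

test_that("NSM preconditions are enforced", {
  dessert <- dessert_scenario()
  expect_error(necessity(dessert, c(G = 1, C = 1, B = 0), "C&B", s = 0),
               "does not hold")
  expect_error(nsm_score(dessert, c(G = 1, C = 0, B = 1), "C", s = 0),
               "does not hold")
  ## zero-mass cause-absent region at s = 1 returns 0, not an error
  expect_equal(necessity(dessert, dessert_actual, "C&B", s = 1), 0)
  expect_equal(sufficiency(dessert, dessert_actual, "C&B", s = 1), 0)
})
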