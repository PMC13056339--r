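## Independent brute-force oracles. These deliberately avoid the package's
## parser, enumeration and scoring code paths: rules are hand-written R
## functions, worlds are enumerated with expand.grid + apply/prod, and the
## weighted correlation goes through stats::cov.wt.

## Hand-written outcome rules for the fixtures (row = named 0/1 vector).
dessert_rule <- function(a) as.integer(a[["G"]] + a[["C"]] + a[["B"]] >= 2)
exp1_rule <- function(a)
  as.integer(a[["low"]] + a[["intermediate"]] + a[["high"]] >= 2)
exp2_rule <- function(a)
  as.integer((a[["A"]] == 1 && a[["B"]] == 1) || (a[["C"]] == 1 && a[["D"]] == 1))

dessert_scenario <- function() {
  causal_scenario(c(G = 0.5, C = 0.8, B = 0.1), "count(G,C,B)>=2",
                  label = "three desserts")
}
dessert_actual <- c(G = 1, C = 1, B = 1)

## All 2^n worlds as a data.frame of 0/1 columns.
oracle_worlds <- function(vars) {
  g <- expand.grid(rep(list(0:1), length(vars)), KEEP.OUT.ATTRS = FALSE)
  names(g) <- vars
  g
}

## World probabilities from per-variable P(value = 1); anchoring is applied
## by the caller by passing mixed probabilities.
oracle_probs <- function(worlds, p1) {
  apply(worlds, 1, function(row)
    prod(ifelse(row == 1, p1[names(row)], 1 - p1[names(row)])))
}

oracle_p1 <- function(priors, actual, s, anchored = NULL) {
  if (is.null(anchored)) anchored <- rep(TRUE, length(priors))
  names(anchored) <- names(priors)
  sapply(names(priors), function(v) {
    if (anchored[[v]]) s * (actual[[v]] == 1) + (1 - s) * priors[[v]]
    else priors[[v]]
  })
}

oracle_indicator <- function(worlds, literals) {
  apply(worlds, 1, function(row) as.integer(all(row[names(literals)] == literals)))
}

## Weighted Pearson correlation via stats::cov.wt (ML normalization).
oracle_cesm <- function(priors, actual, s, rule_fn, literals,
                        anchored = NULL) {
  worlds <- oracle_worlds(names(priors))
  p <- oracle_probs(worlds, oracle_p1(priors, actual, s, anchored))
  x <- oracle_indicator(worlds, literals)
  y <- apply(worlds, 1, rule_fn)
  if (sum(p * x) * (1 - sum(p * x)) < 1e-12 ||
      sum(p * y) * (1 - sum(p * y)) < 1e-12) return(0)
  cw <- stats::cov.wt(cbind(x, y), wt = p / sum(p), method = "ML", cor = TRUE)
  cw$cor[1, 2]
}

## Necessity: among cause-absent worlds (off-candidate variables pinned at
## actual unless resample_off = TRUE), the conditional probability that the
## outcome differs from the actual outcome.
oracle_necessity <- function(priors, actual, s, rule_fn, literals,
                             resample_off = FALSE, anchored = NULL) {
  o_actual <- rule_fn(actual)
  worlds <- oracle_worlds(names(priors))
  p1 <- oracle_p1(priors, actual, s, anchored)
  if (is.null(anchored)) anchored <- setNames(rep(TRUE, length(priors)),
                                              names(priors))
  if (!resample_off) {
    for (v in setdiff(names(priors), names(literals)))
      if (anchored[[v]]) p1[[v]] <- as.numeric(actual[[v]] == 1)
  }
  p <- oracle_probs(worlds, p1)
  absent <- oracle_indicator(worlds, literals) == 0
  y <- apply(worlds, 1, rule_fn)
  denom <- sum(p[absent])
  if (denom <= 0) return(0)
  sum(p[absent] * (y[absent] != o_actual)) / denom
}

## Sufficiency: condition on cause absent & outcome absent, force the
## cause's literals, and ask how often the outcome is restored.
oracle_sufficiency <- function(priors, actual, s, rule_fn, literals,
                               anchored = NULL) {
  o_actual <- rule_fn(actual)
  worlds <- oracle_worlds(names(priors))
  p <- oracle_probs(worlds, oracle_p1(priors, actual, s, anchored))
  y <- apply(worlds, 1, rule_fn)
  absent <- oracle_indicator(worlds, literals) == 0
  cond <- absent & (y != o_actual)
  denom <- sum(p[cond])
  if (denom <= 0) return(0)
  restored <- apply(worlds[cond, , drop = FALSE], 1, function(row) {
    row[names(literals)] <- literals
    rule_fn(row) == o_actual
  })
  sum(p[cond] * restored) / denom
}

oracle_nsm <- function(priors, actual, s, rule_fn, literals,
                       resample_off = FALSE, anchored = NULL) {
  pri <- prod(ifelse(literals == 1, priors[names(literals)],
                     1 - priors[names(literals)]))
  nec <- oracle_necessity(priors, actual, s, rule_fn, literals,
                          resample_off, anchored)
  suf <- oracle_sufficiency(priors, actual, s, rule_fn, literals, anchored)
  pri * suf + (1 - pri) * nec
}

## Mixture loss rule for the augmented (w) model, as a hand-written function
## over the original variables plus the interpretation coin `I`.
exp2_loss_rule <- function(strong_vars) {
  function(a) {
    strong <- as.integer(all(a[strong_vars] == 0))
    classical <- as.integer(exp2_rule(a) == 0)
    if (a[["I"]] == 1) strong else classical
  }
}

## Priors/actual extended with the interpretation coin at prior w.
with_coin <- function(priors, actual, w) {
  list(priors = c(priors, I = w),
       actual = c(actual, I = 1),
       anchored = setNames(c(rep(TRUE, length(priors)), FALSE),
                           c(names(priors), "I")))
}

exp1_priors <- c(low = 0.05, intermediate = 0.5, high = 0.95)
exp2_priors <- c(A = 0.7, B = 0.1, C = 0.2, D = 0.9)

## Evaluate a parsed rule directly (internal helper of the package).
rule_eval_test <- function(rule, a) pluralcause:::rule_eval(rule, a)

## Literal map of a cause string, for feeding the oracles.
as_cause_literals <- function(cs) parse_cause(cs)$literals

`%||%` <- function(a, b) if (is.null(a)) b else a

## Delta-method standard error of the sample correlation of two binary
## variables with joint moments (px, py, p11), at sample size n. The
## correlation is a smooth function of the moment vector (E[x], E[y],
## E[xy]); its asymptotic variance is g' Sigma g / n with Sigma the exact
## covariance of (x, y, xy) and g the gradient, taken numerically.
binary_cor_se <- function(px, py, p11, n) {
  r_of <- function(m) {
    v <- m[1] * (1 - m[1]) * m[2] * (1 - m[2])
    if (v <= 0) return(0)
    (m[3] - m[1] * m[2]) / sqrt(v)
  }
  m <- c(px, py, p11)
  g <- numeric(3)
  h <- 1e-6
  for (i in 1:3) {
    up <- m; up[i] <- up[i] + h
    dn <- m; dn[i] <- dn[i] - h
    g[i] <- (r_of(up) - r_of(dn)) / (2 * h)
  }
  Sigma <- matrix(c(
    px * (1 - px),  p11 - px * py,  p11 * (1 - px),
    p11 - px * py,  py * (1 - py),  p11 * (1 - py),
    p11 * (1 - px), p11 * (1 - py), p11 * (1 - p11)), 3, 3)
  sqrt(max(drop(t(g) %*% Sigma %*% g), 0) / n)
}

## SE of the MC CESM estimate for a cause, from the exact distribution.
cesm_mc_se <- function(scenario, actual, cause, s, n) {
  d <- enumerate_distribution(scenario, actual, s)
  x <- cause_indicator(parse_cause(cause), d$worlds)
  px <- sum(d$prob * x); py <- sum(d$prob * d$outcome)
  p11 <- sum(d$prob * x * d$outcome)
  binary_cor_se(px, py, p11, n)
}

## Temp file cleaned up when the calling test finishes.
withr_local_tempfile <- function(ext, env = parent.frame()) {
  path <- tempfile(fileext = ext)
  withr::defer(unlink(path), envir = env)
  path
}
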