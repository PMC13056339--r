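## Shared plumbing for the NSM's two conditional probabilities. Both are
## computed by exact enumeration under a measure in which:
##   - the cause's own variables follow their sampling propensities,
##   - off-candidate anchored variables are either held at their actual value
##     (fixed_at_actual, the default) or follow their propensities
##     (resampled),
##   - never-anchored variables (e.g. the loss-interpretation coin) always
##     follow their prior, in every mode.

nsm_measure_p1 <- function(scenario, actual, cause, s, fix_off_candidate) {
  v <- scenario$variables
  in_cause <- v$name %in% names(cause$literals)
  p1 <- propensity_one(scenario, actual, s)
  if (fix_off_candidate) {
    fix <- !in_cause & v$anchored
    p1[fix] <- as.numeric(actual[v$name[fix]] == 1)
  }
  p1
}

check_cause_actual <- function(cause, scenario, actual) {
  cause <- check_cause(cause, scenario)
  if (cause_indicator(cause, actual) != 1L)
    stop("the cause does not hold in the actual world")
  cause
}

zero_mass_note <- function(which) {
  if (isTRUE(getOption("pluralcause.verbose", FALSE)))
    message("zero-mass ", which, " region; returning 0 by convention")
}

#' NSM necessity score
#'
#' The probability that removing the cause removes the outcome: among
#' counterfactual worlds where the (possibly plural) cause fails to hold,
#' the propensity-weighted fraction whose outcome differs from the actual
#' outcome. In the default `fixed_at_actual` mode the off-candidate
#' variables are held at their actual values, so only the cause's own
#' variables vary; in `resampled` mode they are marginalized by their
#' sampling propensities as well. If the cause-absent region has zero
#' probability mass (e.g. at `s = 1`), the score is 0 by convention.
#'
#' @inheritParams cesm_score
#' @param off_candidate_mode `"fixed_at_actual"` (default) or `"resampled"`.
#' @return probability in \[0,1\].
#' @examples
#' dessert <- causal_scenario(c(G = 0.5, C = 0.8, B = 0.1), "count(G,C,B)>=2")
#' necessity(dessert, c(G = 1, C = 1, B = 1), "C&B", s = 0)  # 0.18 / 0.92
#' @export
necessity <- function(scenario, actual, cause, s,
                      off_candidate_mode = c("fixed_at_actual", "resampled")) {
  off_candidate_mode <- match.arg(off_candidate_mode)
  cause <- check_cause_actual(cause, scenario, actual)
  o_actual <- evaluate_outcome(scenario, actual)
  worlds <- world_matrix(scenario_vars(scenario))
  p1 <- nsm_measure_p1(scenario, actual, cause, s,
                       fix_off_candidate = off_candidate_mode == "fixed_at_actual")
  prob <- world_probs(worlds, p1)
  absent <- cause_indicator(cause, worlds) == 0L
  mass <- sum(prob[absent])
  if (mass <= 0) {
    zero_mass_note("necessity")
    return(0)
  }
  outcome <- evaluate_outcome(scenario, worlds)
  sum(prob[absent] * (outcome[absent] != o_actual)) / mass
}

#' NSM sufficiency score
#'
#' The probability that adding the cause produces the outcome: condition on
#' counterfactual worlds where both the cause and the outcome differ from
#' their actual values, intervene by setting the cause's variables to their
#' required values (leaving everything else at its world value), and return
#' the propensity-weighted fraction whose post-intervention outcome matches
#' the actual outcome. All variables are sampled by their propensities when
#' forming the conditioning set. A zero-mass conditioning set returns 0.
#'
#' @inheritParams necessity
#' @return probability in \[0,1\].
#' @export
sufficiency <- function(scenario, actual, cause, s) {
  cause <- check_cause_actual(cause, scenario, actual)
  o_actual <- evaluate_outcome(scenario, actual)
  worlds <- world_matrix(scenario_vars(scenario))
  p1 <- propensity_one(scenario, actual, s)
  prob <- world_probs(worlds, p1)
  outcome <- evaluate_outcome(scenario, worlds)
  cond <- cause_indicator(cause, worlds) == 0L & outcome != o_actual
  mass <- sum(prob[cond])
  if (mass <= 0) {
    zero_mass_note("sufficiency conditioning")
    return(0)
  }
  forced <- worlds[cond, , drop = FALSE]
  for (v in names(cause$literals)) forced[, v] <- cause$literals[[v]]
  post <- evaluate_outcome(scenario, forced)
  sum(prob[cond] * (post == o_actual)) / mass
}

#' Necessity-Sufficiency Model (NSM) score
#'
#' The holistic NSM score of a (possibly plural) cause: the convex
#' combination of its sufficiency and necessity, weighted by the cause's
#' prior probability,
#' `combined = prior * sufficiency + (1 - prior) * necessity`.
#' Rare causes (low prior) are thus scored mostly by necessity, common
#' causes mostly by sufficiency; since a conjunction is always at most as
#' probable as its conjuncts, plural causes shift weight toward necessity.
#'
#' @inheritParams necessity
#' @return an object of class `nsm_score`: list with `cause`, `necessity`,
#'   `sufficiency`, `prior`, `combined`, `off_candidate_mode`, `s`.
#' @examples
#' dessert <- causal_scenario(c(G = 0.5, C = 0.8, B = 0.1), "count(G,C,B)>=2")
#' nsm_score(dessert, c(G = 1, C = 1, B = 1), "C&B", s = 0)
#' @export
nsm_score <- function(scenario, actual, cause, s,
                      off_candidate_mode = c("fixed_at_actual", "resampled")) {
  off_candidate_mode <- match.arg(off_candidate_mode)
  cause <- check_cause_actual(cause, scenario, actual)
  nec <- necessity(scenario, actual, cause, s, off_candidate_mode)
  suf <- sufficiency(scenario, actual, cause, s)
  pri <- cause_prior(cause, scenario)
  structure(list(cause = cause, necessity = nec, sufficiency = suf,
                 prior = pri, combined = pri * suf + (1 - pri) * nec,
                 off_candidate_mode = off_candidate_mode, s = s),
            class = "nsm_score")
}

#' @export
print.nsm_score <- function(x, ...) {
  cat(sprintf("NSM score for %s (s = %g, %s)\n", format(x$cause), x$s,
              x$off_candidate_mode))
  cat(sprintf("  necessity   = %.4f\n", x$necessity))
  cat(sprintf("  sufficiency = %.4f\n", x$sufficiency))
  cat(sprintf("  prior       = %.4f\n", x$prior))
  cat(sprintf("  combined    = %.4f\n", x$combined))
  invisible(x)
}
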