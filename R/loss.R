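#' Strong (homogeneous) loss rule
#'
#' When people explain a loss they may represent the losing conditions not as
#' the classical negation of the winning rule but in the "homogeneous" way
#' natural language negates plurals ("the boys didn't do their homework" =
#' none of them did). The strong loss rule is the conjunction of `!X` over
#' exactly those variables whose actual value is 0 -- the most homogeneous
#' negation that does not contradict the established facts of the round. For
#' a round lost with every draw absent this is the full conjunction of
#' negations; when some variable was actually present it is excluded.
#'
#' @param scenario a [causal_scenario()].
#' @param actual named 0/1 vector; must be a losing round (rule evaluates
#'   to 0) with at least one absent variable.
#' @return an `outcome_rule` for the strong losing conditions.
#' @examples
#' exp2 <- causal_scenario(c(A = 0.7, B = 0.1, C = 0.2, D = 0.9),
#'                         "(A&B)|(C&D)")
#' strong_loss_rule(exp2, c(A = 0, B = 0, C = 1, D = 0))$text  # "!A&!B&!D"
#' @export
strong_loss_rule <- function(scenario, actual) {
  stopifnot(inherits(scenario, "causal_scenario"))
  a <- check_assignment(scenario, actual)
  if (evaluate_outcome(scenario, actual) != 0L)
    stop("strong loss rule requires a losing round (actual outcome is a win)")
  absent <- names(a)[a == 0]
  if (!length(absent))
    stop("strong loss rule undefined: no variable is absent in the actual world")
  parse_rule(paste0("!", absent, collapse = "&"), scenario_vars(scenario))
}

## Pick a fresh variable name for the interpretation coin.
fresh_var_name <- function(base, taken) {
  nm <- base
  while (nm %in% taken) nm <- paste0(nm, "_")
  nm
}

#' Augment a losing-round scenario with the loss-interpretation mixture
#'
#' Builds the scenario under which losing rounds are scored. An extra
#' independent binary variable `I` with prior `w` decides, fresh in every
#' counterfactual world, how that world's loss is read: with probability `w`
#' non-classically via the strong homogeneous rule ([strong_loss_rule()]),
#' otherwise classically as the negation of the winning rule. Worlds that
#' are not losses under the selected reading count as wins. The outcome of
#' the augmented scenario is LOSS, so all CESM/NSM machinery applies
#' unchanged with the loss as the scored outcome; at `w = 0` everything
#' reduces exactly to the classical negation.
#'
#' `I` is never anchored to an actual value: the interpretation decision is
#' per counterfactual world, not a stable fact of the actual round, so the
#' stability parameter `s` does not apply to it (and it is likewise
#' marginalized, never fixed, in NSM conditioning).
#'
#' @param scenario a [causal_scenario()] whose rule describes winning.
#' @param actual named 0/1 vector; must be a losing round.
#' @param w probability in \[0,1\] of the non-classical reading.
#' @return a list with elements `scenario` (the augmented
#'   [causal_scenario()], outcome = LOSS), `actual` (the actual world
#'   extended with `I = 1`; both readings agree that the actual round is a
#'   loss, so the stored value is inert), and `interpretation_var` (name of
#'   the added variable).
#' @export
augment_with_interpretation <- function(scenario, actual, w) {
  stopifnot(inherits(scenario, "causal_scenario"),
            length(w) == 1L, w >= 0, w <= 1)
  a <- check_assignment(scenario, actual)
  if (evaluate_outcome(scenario, actual) != 0L)
    stop("loss interpretation applies to losing rounds only")
  strong <- strong_loss_rule(scenario, actual)
  iname <- fresh_var_name("I", scenario_vars(scenario))
  vars <- rbind(scenario$variables[c("name", "prior", "anchored")],
                data.frame(name = iname, prior = w, anchored = FALSE))
  loss_text <- sprintf("(%s&(%s))|(!%s&!(%s))",
                       iname, strong$text, iname, scenario$rule$text)
  aug <- causal_scenario(vars, loss_text,
                         label = paste0(scenario$label,
                                        sprintf(" [loss, w = %g]", w)))
  actual_aug <- c(a, stats::setNames(1L, iname))
  list(scenario = aug, actual = actual_aug, interpretation_var = iname)
}

#' Classical-negation loss scenario
#'
#' The unaugmented baseline for losing rounds: same variables, outcome equal
#' to the classical negation of the winning rule. Equivalent to the
#' `w = 0` limit of [augment_with_interpretation()].
#'
#' @param scenario a [causal_scenario()] whose rule describes winning.
#' @return a [causal_scenario()] whose outcome is the classical LOSS.
#' @export
classical_loss_scenario <- function(scenario) {
  causal_scenario(scenario$variables[c("name", "prior", "anchored")],
                  paste0("!(", scenario$rule$text, ")"),
                  label = paste0(scenario$label, " [loss, classical]"))
}
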