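#' Per-variable counterfactual sampling propensity
#'
#' In a sampled counterfactual world, a variable keeps its actual value with
#' probability `s` (the stability parameter) and is otherwise resampled from
#' its prior. Collapsing the two stages gives the mixture propensity
#' `s * 1[value = actual] + (1 - s) * (prior if value = 1 else 1 - prior)`,
#' which is what this function returns. The propensities of the two values
#' sum to 1; at `s = 0` they reduce to the prior, at `s = 1` to a point mass
#' on the actual value.
#'
#' @param prior prior probability of value 1, in \[0,1\].
#' @param actual_value actual value of the variable, 0 or 1.
#' @param value candidate value, 0 or 1.
#' @param s stability in \[0,1\].
#' @return probability of drawing `value`.
#' @export
value_propensity <- function(prior, actual_value, value, s) {
  stopifnot(all(prior >= 0 & prior <= 1), all(s >= 0 & s <= 1),
            all(actual_value %in% c(0, 1)), all(value %in% c(0, 1)))
  s * (value == actual_value) + (1 - s) * ifelse(value == 1, prior, 1 - prior)
}

## Probability that each scenario variable takes value 1 under the sampling
## measure: anchored variables mix s toward actual, never-anchored variables
## are always drawn fresh from their prior.
propensity_one <- function(scenario, actual, s) {
  v <- scenario$variables
  p1 <- numeric(nrow(v))
  for (i in seq_len(nrow(v))) {
    p1[i] <- if (v$anchored[i]) {
      value_propensity(v$prior[i], actual[[v$name[i]]], 1, s)
    } else {
      v$prior[i]
    }
  }
  names(p1) <- v$name
  p1
}

## All 2^n assignments as a 0/1 matrix with named columns.
world_matrix <- function(vars) {
  grid <- expand.grid(rep(list(0:1), length(vars)), KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(grid)
  colnames(m) <- vars
  storage.mode(m) <- "integer"
  m
}

## Probability of each row of a world matrix under independent per-variable
## value-1 probabilities p1.
world_probs <- function(worlds, p1) {
  p <- rep(1, nrow(worlds))
  for (v in colnames(worlds)) {
    p <- p * ifelse(worlds[, v] == 1L, p1[[v]], 1 - p1[[v]])
  }
  p
}

#' Exact counterfactual distribution over worlds
#'
#' Enumerates all `2^n` assignments to the scenario's variables and attaches
#' to each its propensity product and its outcome under the scenario rule.
#' This is the exact counterpart of Monte-Carlo sampling
#' ([sample_worlds()]) and the default scoring path for the CESM and NSM.
#'
#' @param scenario a [causal_scenario()].
#' @param actual named 0/1 vector, the actual world. Variables flagged as
#'   never anchored may be omitted.
#' @param s stability in \[0,1\].
#' @return an object of class `cf_distribution` with elements `worlds`
#'   (2^n x n 0/1 matrix), `prob` (summing to 1), `outcome` (0/1 per world),
#'   `s`, and `actual`.
#' @export
enumerate_distribution <- function(scenario, actual, s) {
  stopifnot(inherits(scenario, "causal_scenario"),
            length(s) == 1L, s >= 0, s <= 1)
  vars <- scenario_vars(scenario)
  if (length(vars) > 20L)
    stop("enumeration limited to 20 variables (2^n worlds)")
  anchored_vars <- scenario$variables$name[scenario$variables$anchored]
  if (!all(anchored_vars %in% names(actual)))
    stop("actual world is missing variable(s): ",
         paste(setdiff(anchored_vars, names(actual)), collapse = ", "))
  worlds <- world_matrix(vars)
  p1 <- propensity_one(scenario, actual, s)
  prob <- world_probs(worlds, p1)
  structure(list(worlds = worlds, prob = prob,
                 outcome = evaluate_outcome(scenario, worlds),
                 s = s, actual = actual),
            class = "cf_distribution")
}

#' @export
print.cf_distribution <- function(x, ...) {
  cat(sprintf("Counterfactual distribution over %d worlds (s = %g)\n",
              nrow(x$worlds), x$s))
  cat(sprintf("  P(outcome = 1) = %.4f\n", sum(x$prob * x$outcome)))
  invisible(x)
}

#' @export
as.data.frame.cf_distribution <- function(x, ...) {
  data.frame(x$worlds, probability = x$prob, outcome = x$outcome)
}

#' Monte-Carlo counterfactual world sample
#'
#' Draws `n_samples` i.i.d. counterfactual worlds by sampling each variable
#' independently from its [value_propensity()] (never-anchored variables from
#' their prior). Mirrors the procedure of simulating many possible rounds of
#' the game; exact enumeration is the oracle this converges to.
#'
#' @inheritParams enumerate_distribution
#' @param n_samples number of worlds to draw (default `1e5`).
#' @param seed required integer seed; sampling never touches global RNG
#'   state outside this call.
#' @return an object of class `world_sample` with elements `worlds`
#'   (n_samples x n matrix), `outcome`, `s`, `n_samples`, `seed`.
#' @export
sample_worlds <- function(scenario, actual, s, n_samples = 1e5, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required for sampling")
  stopifnot(n_samples >= 1)
  vars <- scenario_vars(scenario)
  p1 <- propensity_one(scenario, actual, s)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m <- matrix(0L, nrow = n_samples, ncol = length(vars),
              dimnames = list(NULL, vars))
  for (v in vars) m[, v] <- as.integer(stats::runif(n_samples) < p1[[v]])
  structure(list(worlds = m, outcome = evaluate_outcome(scenario, m),
                 s = s, n_samples = as.integer(n_samples), seed = seed),
            class = "world_sample")
}

## Save/restore global RNG state so seeded draws are hermetic.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.world_sample <- function(x, ...) {
  cat(sprintf("Counterfactual sample: %d worlds (s = %g, seed = %s)\n",
              x$n_samples, x$s, format(x$seed)))
  cat(sprintf("  empirical P(outcome = 1) = %.4f\n", mean(x$outcome)))
  invisible(x)
}
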