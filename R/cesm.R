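## Probability-weighted Pearson correlation between two binary vectors.
## For binary x, E[x^2] = E[x], so the variance is ex*(1-ex). Degenerate
## (zero-variance) cases return 0 by convention: correlation is undefined
## there and 0 encodes the absence of counterfactual dependence.
weighted_binary_cor <- function(x, y, p, tol = 1e-12) {
  ex <- sum(p * x); ey <- sum(p * y)
  vx <- ex * (1 - ex); vy <- ey * (1 - ey)
  if (vx < tol || vy < tol) return(0)
  (sum(p * x * y) - ex * ey) / sqrt(vx * vy)
}

#' Counterfactual Effect Size Model (CESM) score
#'
#' Scores a (possibly plural) cause as the Pearson correlation between the
#' cause's compound indicator variable and the outcome, across counterfactual
#' worlds sampled with stability `s`. In flat binary structures this
#' correlation is the CESM's measure of causal responsibility. Plural causes
#' are scored holistically: the conjunction is one compound binary variable.
#'
#' Exact mode computes the probability-weighted correlation over the full
#' enumerated counterfactual distribution; Monte-Carlo mode computes the
#' sample correlation across `n_samples` drawn worlds and converges to the
#' exact value. If either the indicator or the outcome is constant across
#' worlds (e.g. at `s = 1`, where the distribution is a point mass on the
#' actual world) the score is 0 by convention.
#'
#' @param scenario a [causal_scenario()].
#' @param actual named 0/1 vector, the actual world.
#' @param cause a [candidate_cause()], cause string, or named 0/1 vector.
#' @param s stability in \[0,1\].
#' @param mode `"exact"` (enumeration) or `"monte_carlo"`.
#' @param n_samples,seed Monte-Carlo sample size and (required) seed.
#' @return an object of class `cesm_score`: list with `cause`, `score`
#'   (in \[-1,1\]), `mode`, `s`.
#' @examples
#' dessert <- causal_scenario(c(G = 0.5, C = 0.8, B = 0.1), "count(G,C,B)>=2")
#' cesm_score(dessert, c(G = 1, C = 1, B = 1), "C&B", s = 0)$score
#' @export
cesm_score <- function(scenario, actual, cause, s,
                       mode = c("exact", "monte_carlo"),
                       n_samples = 1e5, seed = NULL) {
  mode <- match.arg(mode)
  cause <- check_cause(cause, scenario)
  if (mode == "exact") {
    dist <- enumerate_distribution(scenario, actual, s)
    score <- weighted_binary_cor(cause_indicator(cause, dist$worlds),
                                 dist$outcome, dist$prob)
  } else {
    if (is.null(seed)) stop("a seed is required for monte_carlo mode")
    smp <- sample_worlds(scenario, actual, s, n_samples = n_samples,
                         seed = seed)
    score <- sample_binary_cor(cause_indicator(cause, smp$worlds), smp$outcome)
  }
  structure(list(cause = cause, score = score, mode = mode, s = s),
            class = "cesm_score")
}

sample_binary_cor <- function(x, y) {
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  stats::cor(x, y)
}

#' @export
print.cesm_score <- function(x, ...) {
  cat(sprintf("CESM score for %s (s = %g, %s): %.4f\n",
              format(x$cause), x$s, x$mode, x$score))
  invisible(x)
}

## Vectorized exact CESM over many causes sharing one distribution:
## X is a worlds x causes 0/1 indicator matrix. Used by the fitting paths.
cesm_scores_vec <- function(dist, X, tol = 1e-12) {
  p <- dist$prob; y <- dist$outcome
  ex <- as.numeric(crossprod(X, p))
  ey <- sum(p * y)
  exy <- as.numeric(crossprod(X, p * y))
  vx <- ex * (1 - ex); vy <- ey * (1 - ey)
  out <- numeric(ncol(X))
  ok <- vx > tol & vy > tol
  out[ok] <- (exy[ok] - ex[ok] * ey) / sqrt(vx[ok] * vy)
  out
}
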