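## Urn-game experiment fixtures. Experiment 1: three urns, win with two or
## more colored balls. Experiment 2: four urns, two color pairs, win iff
## (A&B)|(C&D); four rounds spanning overdetermined and non-overdetermined
## wins and losses.

## All conjunctions of the queried literals of sizes 1..3 (four-variable
## plurals are excluded as exhaustive descriptions of the round).
default_questions <- function(literals) {
  vars <- names(literals)
  out <- list()
  for (k in seq_len(min(3L, length(vars)))) {
    for (idx in utils::combn(length(vars), k, simplify = FALSE)) {
      out[[length(out) + 1L]] <- candidate_cause(literals[idx])
    }
  }
  out
}

make_round <- function(scenario, label, actual, questions = NULL) {
  a <- check_assignment(scenario, actual)
  win <- evaluate_outcome(scenario, a) == 1L
  ## queried literals: drawn urns (value 1) in wins, white urns (value 0) in
  ## losses
  queried <- if (win) a[a == 1] else a[a == 0]
  if (is.null(questions)) questions <- default_questions(queried)
  questions <- lapply(questions, as_cause)
  for (q in questions) {
    if (cause_indicator(q, a) != 1L)
      stop("question ", format(q), " does not hold in the actual world of round '",
           label, "'")
  }
  keys <- vapply(questions, format, character(1))
  if (anyDuplicated(keys)) stop("duplicate questions in round '", label, "'")
  list(label = label, actual = a, win = win, questions = questions)
}

#' Experiment 1 fixture: three urns, threshold rule
#'
#' Three urns labeled by their colored-ball probabilities -- `low` (0.05),
#' `intermediate` (0.5), `high` (0.95); the player wins with two or more
#' colored balls. One round is queried: the player drew a colored ball from
#' all three urns and won. Questions are the three singulars, the three
#' pairs, and the triple (seven questions).
#'
#' @return an object of class `experiment_spec`: list with `label`,
#'   `scenario`, and `rounds` (each round has `label`, `actual`, `win`,
#'   `questions`).
#' @export
experiment1 <- function() {
  sc <- causal_scenario(c(low = 0.05, intermediate = 0.5, high = 0.95),
                        "count(low,intermediate,high)>=2",
                        label = "experiment 1")
  rounds <- list(win = make_round(sc, "win",
                                  c(low = 1, intermediate = 1, high = 1)))
  structure(list(label = "exp1", scenario = sc, rounds = rounds),
            class = "experiment_spec")
}

exp2_actuals <- list(
  overdetermined_positive = c(A = 1, B = 1, C = 1, D = 1),
  triple_positive         = c(A = 1, B = 1, C = 0, D = 1),
  triple_negative         = c(A = 0, B = 0, C = 1, D = 0),
  overdetermined_negative = c(A = 0, B = 0, C = 0, D = 0)
)

#' Experiment 2 fixture: four urns, disjunction of conjunctions
#'
#' Four urns `A`, `B`, `C`, `D` with colored-ball probabilities 0.7, 0.1,
#' 0.2, 0.9; urns A/B hold one color and C/D the other, and the player wins
#' iff they draw two balls of the same color: `(A&B)|(C&D)`. Four rounds are
#' queried: `overdetermined_positive` (all four colored; win),
#' `triple_positive` (A, B, D colored; win), `triple_negative` (A, B, D
#' white; loss), and `overdetermined_negative` (all four white; loss).
#' Winning rounds query positive literals of the drawn urns, losing rounds
#' negative literals of the white urns; default question sets are all
#' conjunctions of sizes one to three of the queried literals,
#' overridable via `questions`.
#'
#' @param rounds character vector of round labels to include (default all
#'   four, in the order above).
#' @param questions optional named list (by round label) of question lists
#'   (causes as strings or [candidate_cause()] objects) overriding the
#'   defaults.
#' @return an `experiment_spec`; see [experiment1()].
#' @export
experiment2 <- function(rounds = names(exp2_actuals), questions = NULL) {
  unknown <- setdiff(rounds, names(exp2_actuals))
  if (length(unknown))
    stop("unknown round label(s): ", paste(unknown, collapse = ", "))
  sc <- causal_scenario(c(A = 0.7, B = 0.1, C = 0.2, D = 0.9),
                        "(A&B)|(C&D)", label = "experiment 2")
  rl <- lapply(rounds, function(r)
    make_round(sc, r, exp2_actuals[[r]], questions = questions[[r]]))
  names(rl) <- rounds
  structure(list(label = "exp2", scenario = sc, rounds = rl),
            class = "experiment_spec")
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat("Experiment spec '", x$label, "'\n", sep = "")
  print(x$scenario)
  for (r in x$rounds) {
    cat(sprintf("  round '%s' (%s): %d questions\n", r$label,
                if (r$win) "win" else "loss", length(r$questions)))
  }
  invisible(x)
}

## ---- shared scoring context -------------------------------------------------
## Precomputes, per round, the scenario actually scored (base for wins,
## interpretation-augmented for losses), its world matrix and outcomes, and
## the question indicator matrix, so that grid fits only redo the cheap
## per-(s, w) probability work.

round_context <- function(spec, round) {
  r <- spec$rounds[[round]]
  if (r$win) {
    sc <- spec$scenario; actual <- r$actual; iname <- NULL
  } else {
    aug <- augment_with_interpretation(spec$scenario, r$actual, w = 0.5)
    sc <- aug$scenario; actual <- aug$actual; iname <- aug$interpretation_var
  }
  worlds <- world_matrix(scenario_vars(sc))
  X <- vapply(r$questions, cause_indicator, integer(nrow(worlds)),
              world = worlds)
  keys <- vapply(r$questions, format, character(1))
  colnames(X) <- keys
  list(round = round, win = r$win, scenario = sc, actual = actual,
       iname = iname, worlds = worlds, X = X,
       outcome = evaluate_outcome(sc, worlds),
       o_actual = evaluate_outcome(sc, actual),
       questions = r$questions, keys = keys,
       base_scenario = spec$scenario)
}

ctx_prob <- function(ctx, s, w) {
  p1 <- propensity_one(ctx$scenario, ctx$actual, s)
  if (!is.null(ctx$iname)) p1[[ctx$iname]] <- w
  world_probs(ctx$worlds, p1)
}

## Exact model scores for all questions of a round at (s, w).
score_round <- function(ctx, model, s, w = 0,
                        off_candidate_mode = "fixed_at_actual") {
  prob <- ctx_prob(ctx, s, w)
  if (model == "cesm") {
    dist <- list(prob = prob, outcome = ctx$outcome)
    scores <- cesm_scores_vec(dist, ctx$X)
    names(scores) <- ctx$keys
    return(scores)
  }
  ## NSM: per-question conditional probabilities over the shared worlds
  X <- ctx$X
  v <- ctx$scenario$variables
  p1 <- propensity_one(ctx$scenario, ctx$actual, s)
  if (!is.null(ctx$iname)) p1[[ctx$iname]] <- w
  nec <- suf <- pri <- numeric(length(ctx$keys))
  for (j in seq_along(ctx$questions)) {
    q <- ctx$questions[[j]]
    absent <- X[, j] == 0L
    ## necessity measure: off-candidate anchored variables pinned at actual
    if (off_candidate_mode == "fixed_at_actual") {
      p1n <- p1
      fix <- !(v$name %in% names(q$literals)) & v$anchored
      p1n[fix] <- as.numeric(ctx$actual[v$name[fix]] == 1)
      pn <- world_probs(ctx$worlds, p1n)
    } else {
      pn <- prob
    }
    mn <- sum(pn[absent])
    nec[j] <- if (mn > 0)
      sum(pn[absent] * (ctx$outcome[absent] != ctx$o_actual)) / mn else 0
    ## sufficiency: condition on cause absent & outcome absent, then force
    cond <- absent & ctx$outcome != ctx$o_actual
    ms <- sum(prob[cond])
    if (ms > 0) {
      forced <- ctx$worlds[cond, , drop = FALSE]
      for (nm in names(q$literals)) forced[, nm] <- q$literals[[nm]]
      post <- evaluate_outcome(ctx$scenario, forced)
      suf[j] <- sum(prob[cond] * (post == ctx$o_actual)) / ms
    } else suf[j] <- 0
    pri[j] <- cause_prior(q, ctx$base_scenario)
  }
  scores <- pri * suf + (1 - pri) * nec
  names(scores) <- ctx$keys
  attr(scores, "necessity") <- stats::setNames(nec, ctx$keys)
  attr(scores, "sufficiency") <- stats::setNames(suf, ctx$keys)
  attr(scores, "prior") <- stats::setNames(pri, ctx$keys)
  scores
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Model prediction table for an experiment
#'
#' Computes exact CESM or NSM scores for every question of every round of an
#' experiment spec at given parameter values. Losing rounds are scored under
#' the loss-interpretation mixture with weight `w` (`w = 0` is classical
#' negation); `w` does not affect winning rounds. If `gamma` is supplied a
#' `scaled` column with `pmax(score, 0)^gamma` is added.
#'
#' @param spec an `experiment_spec` from [experiment1()] / [experiment2()].
#' @param model `"cesm"` or `"nsm"`.
#' @param s stability in \[0,1\].
#' @param w non-classical loss weight in \[0,1\] (losing rounds only).
#' @param gamma optional scaling exponent (> 0).
#' @param off_candidate_mode NSM conditioning mode, see [necessity()].
#' @return a data.frame with columns `scenario`, `round`, `cause`, `model`,
#'   `s`, `interpretation_weight`, `score` (plus `necessity`,
#'   `sufficiency`, `prior` for the NSM, and `scaled` when `gamma` is
#'   given).
#' @examples
#' head(prediction_table(experiment1(), "cesm", s = 0.89))
#' @export
prediction_table <- function(spec, model = c("cesm", "nsm"), s, w = 0,
                             gamma = NULL,
                             off_candidate_mode = c("fixed_at_actual",
                                                    "resampled")) {
  model <- match.arg(model)
  off_candidate_mode <- match.arg(off_candidate_mode)
  stopifnot(inherits(spec, "experiment_spec"),
            s >= 0, s <= 1, w >= 0, w <= 1)
  rows <- lapply(names(spec$rounds), function(r) {
    ctx <- round_context(spec, r)
    scores <- score_round(ctx, model, s, w, off_candidate_mode)
    df <- data.frame(scenario = spec$label, round = r, cause = ctx$keys,
                     model = model, s = s,
                     interpretation_weight = if (ctx$win) NA_real_ else w,
                     score = as.numeric(scores), stringsAsFactors = FALSE)
    if (model == "nsm") {
      df$necessity <- as.numeric(attr(scores, "necessity"))
      df$sufficiency <- as.numeric(attr(scores, "sufficiency"))
      df$prior <- as.numeric(attr(scores, "prior"))
    }
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(gamma)) out$scaled <- scale_prediction(out$score, gamma)
  out
}
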