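#' Define a causal scenario
#'
#' A causal scenario is a "flat" structural causal model: a set of independent
#' binary exogenous variables, each with a marginal prior probability (its
#' "normality"), and a Boolean outcome rule over those variables. All scoring
#' in the package (CESM, NSM, loss models) is defined relative to such a
#' scenario together with an actual world.
#'
#' @param variables a data frame with columns `name` (unique identifiers) and
#'   `prior` (probability in \[0,1\] that the variable takes value 1), or a
#'   named numeric vector of priors. An optional logical column `anchored`
#'   marks variables that are anchored to their actual value with probability
#'   `s` during counterfactual sampling (the default); non-anchored variables
#'   are resampled fresh from their prior in every counterfactual world.
#' @param rule an outcome rule: either a string in the rule grammar (see
#'   [parse_rule()]) or an object returned by `parse_rule()`.
#' @param label free-text label for the scenario.
#' @return an object of class `causal_scenario`.
#' @examples
#' dessert <- causal_scenario(c(G = 0.5, C = 0.8, B = 0.1),
#'                            "count(G,C,B)>=2", label = "three desserts")
#' evaluate_outcome(dessert, c(G = 1, C = 1, B = 0))
#' @export
causal_scenario <- function(variables, rule, label = "") {
  if (is.numeric(variables) && !is.null(names(variables))) {
    variables <- data.frame(name = names(variables), prior = unname(variables),
                            stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(variables),
            all(c("name", "prior") %in% names(variables)))
  variables$name <- as.character(variables$name)
  if (nrow(variables) < 1L)
    stop("a scenario needs at least one variable")
  if (anyDuplicated(variables$name))
    stop("variable names must be unique")
  if (any(!is.finite(variables$prior) | variables$prior < 0 | variables$prior > 1))
    stop("priors must lie in [0, 1]")
  if (is.null(variables$anchored)) variables$anchored <- TRUE
  if (is.character(rule)) rule <- parse_rule(rule, variables$name)
  stopifnot(inherits(rule, "outcome_rule"))
  missing_vars <- setdiff(rule$vars, variables$name)
  if (length(missing_vars))
    stop("rule references undeclared variable(s): ",
         paste(missing_vars, collapse = ", "))
  structure(list(variables = variables, rule = rule, label = label),
            class = "causal_scenario")
}

#' @export
print.causal_scenario <- function(x, ...) {
  cat("Causal scenario", if (nzchar(x$label)) paste0("'", x$label, "'"), "\n")
  cat("  rule:", x$rule$text, "\n")
  cat("  variables:\n")
  for (i in seq_len(nrow(x$variables))) {
    v <- x$variables[i, ]
    cat(sprintf("    %s  P = %g%s\n", v$name, v$prior,
                if (!v$anchored) "  (never anchored)" else ""))
  }
  invisible(x)
}

scenario_vars <- function(scenario) scenario$variables$name

## ---- rule parsing -----------------------------------------------------------
## Grammar (precedence ! > & > |, whitespace insignificant):
##   expr   := term ('|' term)*
##   term   := factor ('&' factor)*
##   factor := '!' factor | '(' expr ')' | 'count' '(' ident,+ ')' '>=' int | ident
## count(v1,...,vk)>=m is first-class threshold syntax; it is translated to
## (v1+...+vk) >= m so that both forms evaluate identically.

rule_tokenize <- function(text) {
  tokens <- list()
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("&", "|", "!", "(", ")", ",")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, value = ch, pos = i)
      i <- i + 1L
    } else if (ch == ">") {
      if (substr(text, i + 1L, i + 1L) != "=")
        stop(sprintf("rule syntax error at position %d: expected '>='", i))
      tokens[[length(tokens) + 1L]] <- list(type = ">=", value = ">=", pos = i)
      i <- i + 2L
    } else if (grepl("^[A-Za-z_]$", ch)) {
      m <- regmatches(substr(text, i, n),
                      regexpr("^[A-Za-z_][A-Za-z0-9_.]*", substr(text, i, n)))
      tokens[[length(tokens) + 1L]] <-
        list(type = if (m == "count") "count" else "ident", value = m, pos = i)
      i <- i + nchar(m)
    } else if (grepl("^[0-9]$", ch)) {
      m <- regmatches(substr(text, i, n), regexpr("^[0-9]+", substr(text, i, n)))
      tokens[[length(tokens) + 1L]] <- list(type = "int", value = m, pos = i)
      i <- i + nchar(m)
    } else {
      stop(sprintf("rule syntax error at position %d: unexpected character '%s'",
                   i, ch))
    }
  }
  tokens
}

#' Parse a Boolean outcome rule
#'
#' Parses a rule expression over variable names into an evaluable outcome
#' rule. The grammar supports identifiers, `&` (AND), `|` (OR), `!` (NOT),
#' parentheses, and the threshold form `count(v1,...,vk)>=m`, with precedence
#' `!` > `&` > `|`. Whitespace is insignificant. Syntax errors and unknown
#' variable names are reported with their character position.
#'
#' @param text rule expression, e.g. `"(A&B)|(C&D)"` or `"count(A,B,C)>=2"`.
#' @param variables character vector of declared variable names.
#' @return an object of class `outcome_rule` with elements `text`, `expr`
#'   (a base-R expression), and `vars` (variables referenced).
#' @export
parse_rule <- function(text, variables) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- rule_tokenize(text)
  if (!length(tokens)) stop("empty rule expression")
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { tok <- tokens[[pos]]; pos <<- pos + 1L; tok }
  expect <- function(type) {
    tok <- peek()
    if (is.null(tok))
      stop(sprintf("rule syntax error at position %d: expected '%s', got end of input",
                   nchar(text) + 1L, type))
    if (tok$type != type)
      stop(sprintf("rule syntax error at position %d: expected '%s', got '%s'",
                   tok$pos, type, tok$value))
    advance()
  }
  used <- character()
  check_ident <- function(tok) {
    if (!(tok$value %in% variables))
      stop(sprintf("unknown variable '%s' at position %d", tok$value, tok$pos))
    used <<- union(used, tok$value)
    as.name(tok$value)
  }
  parse_expr <- function() {
    e <- parse_term()
    while (!is.null(peek()) && peek()$type == "|") {
      advance()
      e <- call("|", e, parse_term())
    }
    e
  }
  parse_term <- function() {
    e <- parse_factor()
    while (!is.null(peek()) && peek()$type == "&") {
      advance()
      e <- call("&", e, parse_factor())
    }
    e
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.null(tok))
      stop(sprintf("rule syntax error at position %d: unexpected end of input",
                   nchar(text) + 1L))
    if (tok$type == "!") { advance(); return(call("!", parse_factor())) }
    if (tok$type == "(") {
      advance(); e <- parse_expr(); expect(")"); return(call("(", e))
    }
    if (tok$type == "count") {
      advance(); expect("(")
      ids <- list(check_ident(expect("ident")))
      while (!is.null(peek()) && peek()$type == ",") {
        advance()
        ids[[length(ids) + 1L]] <- check_ident(expect("ident"))
      }
      expect(")"); expect(">=")
      k <- as.integer(expect("int")$value)
      total <- Reduce(function(a, b) call("+", a, b), ids)
      return(call(">=", call("(", total), k))
    }
    if (tok$type == "ident") { advance(); return(check_ident(tok)) }
    stop(sprintf("rule syntax error at position %d: unexpected '%s'",
                 tok$pos, tok$value))
  }
  expr <- parse_expr()
  if (pos <= length(tokens))
    stop(sprintf("rule syntax error at position %d: unexpected '%s'",
                 tokens[[pos]]$pos, tokens[[pos]]$value))
  structure(list(text = text, expr = expr, vars = used), class = "outcome_rule")
}

#' @export
print.outcome_rule <- function(x, ...) {
  cat("Outcome rule:", x$text, "\n")
  invisible(x)
}

## Evaluate a rule on a named 0/1 assignment (scalars) or on a world matrix
## (columns named after variables); returns integer 0/1 of matching length.
rule_eval <- function(rule, assignment) {
  if (is.matrix(assignment)) {
    env <- as.data.frame(assignment)
  } else {
    env <- as.list(assignment)
  }
  missing_vars <- setdiff(rule$vars, names(env))
  if (length(missing_vars))
    stop("assignment is missing variable(s): ",
         paste(missing_vars, collapse = ", "))
  as.integer(eval(rule$expr, envir = env) >= 1 - 1e-9)
}

#' Evaluate the outcome rule of a scenario on a world
#'
#' @param scenario a [causal_scenario()].
#' @param assignment a named 0/1 vector covering all scenario variables, or a
#'   0/1 matrix with one column per variable.
#' @return outcome value(s), 0 or 1. Pure function of the assignment.
#' @export
evaluate_outcome <- function(scenario, assignment) {
  stopifnot(inherits(scenario, "causal_scenario"))
  rule_eval(scenario$rule, assignment)
}

check_assignment <- function(scenario, assignment) {
  vars <- scenario_vars(scenario)
  if (!all(vars %in% names(assignment)))
    stop("assignment is missing variable(s): ",
         paste(setdiff(vars, names(assignment)), collapse = ", "))
  a <- assignment[vars]
  if (any(!a %in% c(0, 1))) stop("assignment values must be 0 or 1")
  a
}

## ---- candidate causes -------------------------------------------------------

#' Candidate (possibly plural) causes
#'
#' A candidate cause is a conjunction of literals: a non-empty map from
#' variable names to required values 0/1. A single literal is a singular
#' cause; two or more literals form a plural (conjunctive) cause scored
#' holistically as one compound binary event. Positive literals describe
#' events that occurred ("drew a colored ball"); negative literals describe
#' absences ("drew a white ball"), used when explaining losses.
#'
#' `candidate_cause(c(A = 1, B = 1))` and `parse_cause("A&B")` are
#' equivalent; the string form uses `&`-joined literals with `!` marking a
#' required value of 0 (e.g. `"!A&!D"`). [format()] serializes back to the
#' canonical string (literals sorted by variable name).
#'
#' @param literals named 0/1 vector: required value per variable.
#' @return an object of class `candidate_cause`.
#' @examples
#' parse_cause("!A&!D")
#' cause_prior(candidate_cause(c(C = 1, B = 1)),
#'             causal_scenario(c(G = 0.5, C = 0.8, B = 0.1), "count(G,C,B)>=2"))
#' @export
candidate_cause <- function(literals) {
  if (length(literals) == 0L)
    stop("a candidate cause must name at least one literal")
  if (is.null(names(literals)) || any(!nzchar(names(literals))))
    stop("literals must be named by variable")
  if (anyDuplicated(names(literals)))
    stop("a variable may appear only once in a cause")
  if (any(!literals %in% c(0, 1)))
    stop("literal values must be 0 or 1")
  lit <- as.integer(literals)
  names(lit) <- names(literals)
  lit <- lit[order(names(lit))]
  structure(list(literals = lit), class = "candidate_cause")
}

#' @rdname candidate_cause
#' @param text cause string, literals joined by `&`, `!` for negated.
#' @export
parse_cause <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(gsub("\\s+", "", text), "&", fixed = TRUE)[[1]]
  if (!length(parts) || any(!nzchar(parts)))
    stop("malformed cause string: '", text, "'")
  neg <- startsWith(parts, "!")
  vars <- sub("^!", "", parts)
  bad <- !grepl("^[A-Za-z_][A-Za-z0-9_.]*$", vars)
  if (any(bad))
    stop("malformed literal '", parts[bad][1], "' in cause string '", text, "'")
  lit <- as.integer(!neg)
  names(lit) <- vars
  candidate_cause(lit)
}

#' @export
format.candidate_cause <- function(x, ...) {
  lit <- x$literals
  paste0(ifelse(lit == 0L, "!", ""), names(lit), collapse = "&")
}

#' @export
print.candidate_cause <- function(x, ...) {
  cat("Candidate cause:", format(x), "\n")
  invisible(x)
}

as_cause <- function(x) {
  if (inherits(x, "candidate_cause")) x
  else if (is.character(x)) parse_cause(x)
  else candidate_cause(x)
}

check_cause <- function(cause, scenario) {
  cause <- as_cause(cause)
  unknown <- setdiff(names(cause$literals), scenario_vars(scenario))
  if (length(unknown))
    stop("cause references unknown variable(s): ",
         paste(unknown, collapse = ", "))
  cause
}

#' Cause indicator on worlds
#'
#' The compound binary variable for a (possibly plural) cause: 1 on a world
#' iff every literal of the cause is satisfied there.
#'
#' @param cause a [candidate_cause()], cause string, or named 0/1 vector.
#' @param world a named 0/1 assignment, or a 0/1 matrix with named columns
#'   (one row per world).
#' @return 0/1 integer vector, one value per world.
#' @export
cause_indicator <- function(cause, world) {
  cause <- as_cause(cause)
  lit <- cause$literals
  if (is.matrix(world)) {
    if (!all(names(lit) %in% colnames(world)))
      stop("world is missing cause variable(s)")
    ok <- rep(TRUE, nrow(world))
    for (v in names(lit)) ok <- ok & (world[, v] == lit[[v]])
    as.integer(ok)
  } else {
    if (!all(names(lit) %in% names(world)))
      stop("world is missing cause variable(s)")
    as.integer(all(world[names(lit)] == lit))
  }
}

#' Prior probability of a cause
#'
#' Product over literals of the variable's prior (for required value 1) or
#' one minus the prior (for required value 0). This is the "normality" weight
#' that arbitrates between necessity and sufficiency in the NSM: the
#' conjunction of two causes is always at most as probable as each alone, so
#' plural causes lean harder on necessity.
#'
#' @inheritParams cause_indicator
#' @param scenario a [causal_scenario()].
#' @return probability in \[0,1\].
#' @export
cause_prior <- function(cause, scenario) {
  cause <- check_cause(cause, scenario)
  lit <- cause$literals
  pri <- scenario$variables$prior[match(names(lit), scenario$variables$name)]
  prod(ifelse(lit == 1L, pri, 1 - pri))
}
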