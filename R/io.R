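#' Read a participant rating table
#'
#' Reads the package's ratings CSV (columns `participant_id`, `experiment`,
#' `round`, `cause`, `rating`) and validates it: ratings must be integers in
#' 1..9, cause strings must parse under the `&`/`!` convention, and -- when a
#' scenario is supplied -- reference only declared variables. Malformed rows
#' are reported by row number.
#'
#' @param path CSV file path.
#' @param scenario optional [causal_scenario()] used to validate cause
#'   variables.
#' @return validated data.frame of ratings.
#' @export
read_ratings <- function(path, scenario = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "experiment", "round", "cause", "rating")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("ratings file is missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop("no data rows in ", path)
  bad <- which(!is.finite(df$rating) | df$rating != round(df$rating) |
                 df$rating < 1 | df$rating > 9)
  if (length(bad))
    stop("invalid rating in row ", bad[1], ": ", df$rating[bad[1]],
         " (ratings must be integers in 1..9)")
  df$rating <- as.integer(df$rating)
  for (cs in unique(df$cause)) {
    cause <- tryCatch(parse_cause(cs), error = function(e)
      stop("malformed cause string '", cs, "': ", conditionMessage(e)))
    if (!is.null(scenario)) {
      unknown <- setdiff(names(cause$literals), scenario_vars(scenario))
      if (length(unknown))
        stop("cause '", cs, "' references unknown variable(s): ",
             paste(unknown, collapse = ", "))
    }
  }
  df
}

#' @rdname read_ratings
#' @param ratings rating data.frame to write.
#' @export
write_ratings <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scenario configuration file
#'
#' Scenario configs are YAML or JSON with keys `variables` (list of
#' `{name, prior}`), `rule` (string in the rule grammar), optional `actual`
#' (map name to 0/1), and optional `label`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return list with elements `scenario` (a [causal_scenario()]) and
#'   `actual` (named 0/1 vector or `NULL`).
#' @export
read_scenario <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$variables) || is.null(cfg$rule))
    stop("scenario config needs 'variables' and 'rule'")
  vars <- data.frame(
    name = vapply(cfg$variables, function(v) as.character(v$name), character(1)),
    prior = vapply(cfg$variables, function(v) as.numeric(v$prior), numeric(1)),
    stringsAsFactors = FALSE)
  scenario <- causal_scenario(vars, cfg$rule, label = cfg$label %||% "")
  actual <- NULL
  if (!is.null(cfg$actual)) {
    actual <- vapply(cfg$actual, as.integer, integer(1))
    actual <- check_assignment(scenario, actual)
  }
  list(scenario = scenario, actual = actual)
}

#' @rdname read_scenario
#' @param scenario a [causal_scenario()].
#' @param actual optional named 0/1 vector.
#' @export
write_scenario <- function(scenario, path, actual = NULL) {
  cfg <- list(
    label = scenario$label,
    variables = lapply(seq_len(nrow(scenario$variables)), function(i)
      list(name = scenario$variables$name[i],
           prior = scenario$variables$prior[i])),
    rule = scenario$rule$text)
  if (!is.null(actual)) cfg$actual <- as.list(actual)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Write a fit report as JSON
#'
#' Serializes a `causal_fit` (parameters, likelihood, information criteria,
#' correlation, per-question table, and grids) to JSON.
#'
#' @param fit a `causal_fit`.
#' @param path output path.
#' @param seed optional seed to record alongside the report.
#' @export
write_fit_report <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "causal_fit"))
  report <- list(
    model = fit$model,
    s = unname(fit$par[["s"]]), w = unname(fit$par[["w"]]),
    gamma = unname(fit$par[["gamma"]]), sigma = unname(fit$par[["sigma"]]),
    loglik = fit$loglik, npar = fit$npar, n_questions = fit$nobs,
    aic = fit$aic, bic = fit$bic, correlation = fit$correlation,
    questions = data.frame(round = fit$means$round, cause = fit$means$cause,
                           observed_mean = fit$means$mean,
                           fitted = as.numeric(fit$fitted)),
    grids = fit$grids)
  if (!is.null(seed)) report$seed <- seed
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Export a counterfactual distribution as CSV
#'
#' One row per world: the variable bits, the propensity-product probability,
#' and the outcome.
#'
#' @param dist a `cf_distribution` from [enumerate_distribution()].
#' @param path output CSV path.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "cf_distribution"))
  utils::write.csv(as.data.frame(dist), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
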