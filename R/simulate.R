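#' Generate synthetic participant ratings
#'
#' Simulates Likert rating datasets with the statistical structure the
#' fitting stage assumes. Each participant i's latent response to question q
#' is `scale_prediction(score_q, gamma) + b_i + e_iq`, with a mean-zero
#' normal participant intercept `b_i` (sd `intercept_sd`, a response-style
#' offset) and mean-zero normal noise `e_iq` (sd `noise_sd`), both in latent
#' \[0,1\] units. The latent response is mapped to the 1-9 scale via
#' `r = 1 + 8 * latent`, rounded to the nearest integer and clipped to
#' \{1..9\}. Deterministic given `seed`.
#'
#' @param spec an `experiment_spec`.
#' @param model `"cesm"` or `"nsm"`.
#' @param s,w,gamma generating ("true") parameters; `w` applies to losing
#'   rounds only.
#' @param n_participants number of simulated participants (>= 1).
#' @param noise_sd,intercept_sd latent-unit standard deviations (>= 0).
#' @param seed required integer seed.
#' @param off_candidate_mode NSM conditioning mode, see [necessity()].
#' @return data.frame with columns `participant_id`, `experiment`, `round`,
#'   `cause`, `rating`, with the generator settings in
#'   `attr(, "generator")`.
#' @examples
#' r <- generate_ratings(experiment1(), "cesm", s = 0.89, gamma = 0.26,
#'                       n_participants = 20, seed = 1)
#' question_means(r)
#' @export
generate_ratings <- function(spec, model = c("cesm", "nsm"), s, w = 0,
                             gamma = 1, n_participants,
                             noise_sd = 0.12, intercept_sd = 0.05, seed,
                             off_candidate_mode = "fixed_at_actual") {
  model <- match.arg(model)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(n_participants >= 1, noise_sd >= 0, intercept_sd >= 0,
            gamma > 0, s >= 0, s <= 1, w >= 0, w <= 1)
  tab <- prediction_table(spec, model, s = s, w = w, gamma = gamma,
                          off_candidate_mode = off_candidate_mode)
  q <- nrow(tab)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  b <- stats::rnorm(n_participants, 0, intercept_sd)
  e <- matrix(stats::rnorm(n_participants * q, 0, noise_sd),
              nrow = n_participants)
  latent <- outer(b, tab$scaled, `+`) + e
  rating <- pmin(9L, pmax(1L, as.integer(round(1 + 8 * latent))))
  out <- data.frame(
    participant_id = rep(sprintf("p%03d", seq_len(n_participants)), times = q),
    experiment = spec$label,
    round = rep(tab$round, each = n_participants),
    cause = rep(tab$cause, each = n_participants),
    rating = as.integer(rating),
    stringsAsFactors = FALSE)
  attr(out, "generator") <- list(model = model, s = s, w = w, gamma = gamma,
                                 noise_sd = noise_sd,
                                 intercept_sd = intercept_sd,
                                 n_participants = as.integer(n_participants),
                                 seed = seed)
  out
}

#' Parameter recovery study
#'
#' Repeatedly simulates rating datasets from known ("true") parameters,
#' refits the model on each replication's question means, and summarizes
#' the recovery error per parameter. The workhorse behind the package's
#' claim that the grid-search fit identifies `s` (and `w`, for losing
#' rounds) from realistic sample sizes.
#'
#' @inheritParams generate_ratings
#' @param reps number of replications (>= 1).
#' @param s_grid,w_grid,gamma_grid fitting grids, passed to
#'   [fit_causal_model()].
#' @return an object of class `recovery_report`: list with `estimates`
#'   (data.frame of per-replication estimates), `truth`, and
#'   `median_abs_error` (named vector over the fitted parameters).
#' @export
recovery_study <- function(spec, model = c("cesm", "nsm"), s, w = 0,
                           gamma = 1, n_participants, reps, seed,
                           noise_sd = 0.12, intercept_sd = 0.05,
                           s_grid = seq(0, 1, by = 0.01),
                           w_grid = NULL,
                           gamma_grid = seq(0.05, 3, by = 0.05)) {
  model <- match.arg(model)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(reps >= 1)
  old <- .Random.seed_save()
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  .Random.seed_restore(old)
  rows <- vector("list", reps)
  for (i in seq_len(reps)) {
    ratings <- generate_ratings(spec, model, s = s, w = w, gamma = gamma,
                                n_participants = n_participants,
                                noise_sd = noise_sd,
                                intercept_sd = intercept_sd,
                                seed = rep_seeds[i])
    fit <- fit_causal_model(question_means(ratings), spec, model,
                            s_grid = s_grid, w_grid = w_grid,
                            gamma_grid = gamma_grid)
    rows[[i]] <- data.frame(rep = i, seed = rep_seeds[i],
                            s = fit$par[["s"]], w = fit$par[["w"]],
                            gamma = fit$par[["gamma"]],
                            sigma = fit$par[["sigma"]],
                            loglik = fit$loglik)
  }
  est <- do.call(rbind, rows)
  truth <- c(s = s, w = if (any(!is.na(est$w))) w else NA_real_,
             gamma = gamma)
  mae <- c(s = stats::median(abs(est$s - s)),
           w = if (!is.na(truth[["w"]]))
             stats::median(abs(est$w - w)) else NA_real_,
           gamma = stats::median(abs(est$gamma - gamma)))
  structure(list(estimates = est, truth = truth, median_abs_error = mae,
                 n_participants = n_participants, reps = reps, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d replications, %d participants each\n",
              x$reps, x$n_participants))
  for (p in names(x$truth)) {
    if (is.na(x$truth[[p]])) next
    cat(sprintf("  %-5s truth = %.3g, median |error| = %.3g\n",
                p, x$truth[[p]], x$median_abs_error[[p]]))
  }
  invisible(x)
}
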