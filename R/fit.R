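#' Power-law scaling of model predictions
#'
#' Model scores are mapped onto the response scale through a scaling
#' exponent gamma: `scaled = max(raw, 0)^gamma`. Gamma absorbs uniform
#' over- or under-shooting of ratings without changing the predicted
#' ordering of questions. Negative raw scores (possible for CESM
#' correlations) are clipped to 0 before exponentiation, where the power
#' transform is undefined.
#'
#' @param raw numeric model score(s).
#' @param gamma exponent, > 0.
#' @return scaled score(s) in \[0,1\] for raw scores in \[-1,1\].
#' @export
scale_prediction <- function(raw, gamma) {
  stopifnot(gamma > 0)
  clipped <- pmax(raw, 0)
  if (any(raw < 0) && isTRUE(getOption("pluralcause.verbose", FALSE)))
    message(sum(raw < 0), " negative score(s) clipped to 0 before scaling")
  clipped^gamma
}

## Ratings live on 1..9; predictions on [0,1]. The affine map (m-1)/8 puts
## observed means on the prediction scale without extra free parameters.
rescale_rating <- function(m) (m - 1) / 8

question_key <- function(round, cause) paste(round, cause, sep = ":")

#' Per-question mean ratings
#'
#' Aggregates a rating dataset (one row per participant x question) to the
#' per-question means the fitting stage consumes.
#'
#' @param ratings data.frame with columns `round`, `cause`, `rating` (and
#'   typically `participant_id`, `experiment`).
#' @return data.frame with columns `round`, `cause`, `mean` (on the 1-9
#'   scale), `n`.
#' @export
question_means <- function(ratings) {
  stopifnot(all(c("round", "cause", "rating") %in% names(ratings)))
  agg <- stats::aggregate(rating ~ round + cause, data = ratings,
                          FUN = function(x) c(mean = mean(x), n = length(x)))
  out <- data.frame(round = agg$round, cause = agg$cause,
                    mean = agg$rating[, "mean"],
                    n = as.integer(agg$rating[, "n"]),
                    stringsAsFactors = FALSE)
  out[order(out$round, out$cause), , drop = FALSE]
}

## Build an exact-mode prediction function over (s, w) for an experiment
## spec. Winning-round scores do not depend on w, so they are cached per s.
make_prediction_fn <- function(spec, model,
                               off_candidate_mode = "fixed_at_actual") {
  ctxs <- lapply(names(spec$rounds), function(r) round_context(spec, r))
  names(ctxs) <- names(spec$rounds)
  win_cache <- new.env(parent = emptyenv())
  function(s, w = 0) {
    out <- lapply(ctxs, function(ctx) {
      if (ctx$win) {
        key <- sprintf("%s|%.17g", ctx$round, s)
        cached <- win_cache[[key]]
        if (!is.null(cached)) return(cached)
        sc <- score_round(ctx, model, s, 0, off_candidate_mode)
        sc <- stats::setNames(as.numeric(sc),
                              question_key(ctx$round, ctx$keys))
        win_cache[[key]] <- sc
        sc
      } else {
        sc <- score_round(ctx, model, s, w, off_candidate_mode)
        stats::setNames(as.numeric(sc), question_key(ctx$round, ctx$keys))
      }
    })
    unlist(unname(out))
  }
}

## Profiled Gaussian log-likelihood: with sigma at its ML value (RMS
## residual), ll = -Q/2 * (log(2 pi sigma^2) + 1).
profile_loglik <- function(sigma2, q) {
  -q / 2 * (log(2 * pi * pmax(sigma2, 1e-20)) + 1)
}

#' Grid-search maximum-likelihood fit
#'
#' The generic fitting engine: maximizes the Gaussian likelihood of rescaled
#' question means `(m - 1)/8` around scaled model predictions
#' `pmax(pred, 0)^gamma` over a finite grid of `(s, w, gamma)`, with the
#' residual standard deviation profiled out in closed form at each grid
#' point. Ties are broken toward smaller `s`, then smaller `w`, then
#' smaller `gamma`. Most users call [fit_causal_model()], which builds the
#' prediction function from an experiment spec; `grid_fit` accepts any
#' prediction function.
#'
#' @param model_fn function of `(s, w)` returning a named numeric vector of
#'   raw predictions; names are `"round:cause"` keys.
#' @param means a [question_means()] data.frame.
#' @param s_grid,w_grid,gamma_grid ascending grids; `w_grid = NULL` fits
#'   without a loss-interpretation weight (`w` fixed at 0 and not counted
#'   as a parameter), and a length-1 `w_grid` fixes `w` at that value
#'   without counting it as fitted (e.g. `w_grid = 0` is the classical
#'   no-w model on losing rounds).
#' @param model_name label stored in the result.
#' @return an object of class `causal_fit`.
#' @export
grid_fit <- function(model_fn, means,
                     s_grid = seq(0, 1, by = 0.01),
                     w_grid = NULL,
                     gamma_grid = seq(0.05, 3, by = 0.05),
                     model_name = "custom") {
  stopifnot(nrow(means) > 0, length(s_grid) > 0, length(gamma_grid) > 0,
            all(gamma_grid > 0))
  keys <- question_key(means$round, means$cause)
  if (anyDuplicated(keys)) stop("duplicate (round, cause) in means")
  obs <- rescale_rating(means$mean)
  q <- length(obs)
  w_values <- if (is.null(w_grid)) 0 else w_grid
  has_w <- length(w_values) > 1L  # w counted as fitted only when searched
  log_gamma_term <- gamma_grid  # exponents
  best <- list(ll = -Inf)
  for (s in s_grid) {
    for (w in w_values) {
      pred <- model_fn(s, w)
      miss <- setdiff(keys, names(pred))
      if (length(miss))
        stop("model predictions missing for: ", paste(miss, collapse = ", "))
      raw <- pred[keys]
      if (any(!is.finite(raw))) stop("non-finite model predictions")
      lp <- log(pmax(raw, 0))  # -Inf for clipped scores; exp() recovers 0
      scaled <- exp(outer(lp, log_gamma_term))  # q x G
      resid <- scaled - obs
      sigma2 <- colMeans(resid^2)
      ll <- profile_loglik(sigma2, q)
      g_best <- which.max(ll)
      if (ll[g_best] > best$ll) {
        best <- list(ll = ll[g_best], s = s, w = w,
                     gamma = gamma_grid[g_best],
                     sigma = sqrt(max(sigma2[g_best], 1e-20)),
                     raw = raw, fitted = scaled[, g_best])
      }
    }
  }
  npar <- 2L + 1L + as.integer(has_w)  # s, gamma, sigma (+ w)
  finalize_fit(best, obs, means, npar, model_name,
               grids = list(s = s_grid, w = w_grid, gamma = gamma_grid),
               has_w = !is.null(w_grid))
}

finalize_fit <- function(best, obs, means, npar, model_name, grids, has_w) {
  q <- length(obs)
  corr <- if (stats::sd(best$fitted) > 0 && stats::sd(obs) > 0)
    stats::cor(best$fitted, obs) else 0
  par <- c(s = best$s, w = if (has_w) best$w else NA_real_,
           gamma = best$gamma, sigma = best$sigma)
  structure(list(model = model_name, par = par, has_w = has_w,
                 loglik = best$ll, npar = npar, nobs = q,
                 aic = 2 * npar - 2 * best$ll,
                 bic = npar * log(q) - 2 * best$ll,
                 correlation = corr,
                 fitted = best$fitted, raw = best$raw,
                 observed = obs, means = means, grids = grids),
            class = "causal_fit")
}

#' Fit a counterfactual causal-selection model to mean ratings
#'
#' The package's central fitting function. Given per-question ratings (or
#' their means) from an urn-game experiment and the experiment's spec, it
#' grid-searches the stability `s`, the loss-interpretation weight `w`
#' (only when losing rounds are present), and the scaling exponent `gamma`
#' for the CESM or NSM by maximum likelihood: observed means are rescaled
#' to \[0,1\] via `(m - 1)/8` and modeled as Gaussian around
#' `pmax(score, 0)^gamma`, with the residual standard deviation profiled
#' out in closed form.
#'
#' @param data a rating dataset (columns `round`, `cause`, `rating`) or a
#'   [question_means()] data.frame (columns `round`, `cause`, `mean`).
#' @param spec an `experiment_spec` ([experiment1()], [experiment2()]).
#' @param model `"cesm"` or `"nsm"`.
#' @param s_grid,w_grid,gamma_grid search grids. `w_grid = NULL` (the
#'   default) fits `w` over `seq(0, 1, 0.01)` when the data contain losing
#'   rounds and omits `w` otherwise; pass a grid explicitly to override.
#' @param off_candidate_mode NSM conditioning mode, see [necessity()].
#' @return an object of class `causal_fit`, with methods `print`,
#'   `summary`, `coef`, `logLik`, `AIC`, `BIC`, `predict`, `fitted`,
#'   `residuals`, and `plot`.
#' @examples
#' spec <- experiment1()
#' ratings <- generate_ratings(spec, "cesm", s = 0.89, gamma = 0.26,
#'                             n_participants = 50, seed = 1)
#' fit <- fit_causal_model(ratings, spec, "cesm",
#'                         s_grid = seq(0.5, 1, 0.05),
#'                         gamma_grid = c(0.1, 0.26, 0.5, 1))
#' coef(fit)
#' @export
fit_causal_model <- function(data, spec, model = c("cesm", "nsm"),
                             s_grid = seq(0, 1, by = 0.01),
                             w_grid = NULL,
                             gamma_grid = seq(0.05, 3, by = 0.05),
                             off_candidate_mode = c("fixed_at_actual",
                                                    "resampled")) {
  model <- match.arg(model)
  off_candidate_mode <- match.arg(off_candidate_mode)
  stopifnot(inherits(spec, "experiment_spec"))
  means <- if ("rating" %in% names(data)) question_means(data) else data
  stopifnot(all(c("round", "cause", "mean") %in% names(means)))
  if (any(means$mean < 1 | means$mean > 9))
    stop("question means must lie on the 1-9 rating scale")
  rounds_in_data <- unique(means$round)
  unknown <- setdiff(rounds_in_data, names(spec$rounds))
  if (length(unknown))
    stop("data contain round(s) absent from the spec: ",
         paste(unknown, collapse = ", "))
  sub <- spec
  sub$rounds <- spec$rounds[rounds_in_data]
  has_loss <- any(!vapply(sub$rounds, `[[`, logical(1), "win"))
  if (is.null(w_grid) && has_loss) w_grid <- seq(0, 1, by = 0.01)
  if (!has_loss) w_grid <- NULL
  fn <- make_prediction_fn(sub, model, off_candidate_mode)
  fit <- grid_fit(fn, means, s_grid = s_grid, w_grid = w_grid,
                  gamma_grid = gamma_grid, model_name = model)
  fit$spec_label <- spec$label
  fit$off_candidate_mode <- if (model == "nsm") off_candidate_mode else NULL
  fit
}

#' Constant-baseline fit
#'
#' A reference model that predicts the same value, `0.5^gamma`, for every
#' question, fitted through `gamma` (and the profiled sigma) by the same
#' likelihood as [fit_causal_model()]. Its correlation with the means is
#' undefined (constant predictor) and reported as 0 by convention.
#'
#' @inheritParams fit_causal_model
#' @param gamma_grid grid for the scaling exponent.
#' @return a `causal_fit` with 2 parameters (gamma, sigma).
#' @export
constant_baseline_fit <- function(data, gamma_grid = seq(0.05, 3, by = 0.05)) {
  means <- if ("rating" %in% names(data)) question_means(data) else data
  obs <- rescale_rating(means$mean)
  q <- length(obs)
  scaled <- outer(rep(0.5, q), gamma_grid, `^`)
  sigma2 <- colMeans((scaled - obs)^2)
  ll <- profile_loglik(sigma2, q)
  g <- which.max(ll)
  best <- list(ll = ll[g], s = NA_real_, w = NA_real_, gamma = gamma_grid[g],
               sigma = sqrt(max(sigma2[g], 1e-20)),
               raw = rep(0.5, q), fitted = scaled[, g])
  fit <- finalize_fit(best, obs, means, npar = 2L, model_name = "constant",
                      grids = list(gamma = gamma_grid), has_w = FALSE)
  fit$par[["s"]] <- NA_real_
  fit$correlation <- 0
  fit
}

#' Linear-combination baseline for plural causes
#'
#' The deflationary null model for pairs: each pair's prediction is the
#' arithmetic mean of the observed mean ratings of its two constituent
#' singular causes (on the raw 1-9 scale). Under this hypothesis a variable
#' contributes the same amount to every plural containing it; the holistic
#' models predict departures from it.
#'
#' @param means a [question_means()] data.frame containing at least the
#'   singular causes of each pair to be predicted.
#' @return data.frame with columns `round`, `cause`, `prediction` (1-9
#'   scale) for every two-literal cause present in `means`.
#' @export
linear_combination_baseline <- function(means) {
  stopifnot(all(c("round", "cause", "mean") %in% names(means)))
  out <- list()
  for (r in unique(means$round)) {
    mr <- means[means$round == r, , drop = FALSE]
    lits <- lapply(mr$cause, function(x) as_cause(x)$literals)
    sizes <- lengths(lits)
    singles <- stats::setNames(mr$mean[sizes == 1L],
                               vapply(lits[sizes == 1L],
                                      function(l) format(candidate_cause(l)),
                                      character(1)))
    for (i in which(sizes == 2L)) {
      parts <- vapply(seq_along(lits[[i]]), function(j)
        format(candidate_cause(lits[[i]][j])), character(1))
      if (!all(parts %in% names(singles)))
        stop("missing singular mean(s) for pair ", mr$cause[i], " in round ",
             r, ": ", paste(setdiff(parts, names(singles)), collapse = ", "))
      out[[length(out) + 1L]] <- data.frame(
        round = r, cause = mr$cause[i],
        prediction = mean(singles[parts]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no pair causes found in means")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare fitted models
#'
#' Tabulates log-likelihood, parameter count, AIC (`2k - 2 logL`), BIC
#' (`k log(Q) - 2 logL` with `Q` the number of questions), and the Pearson
#' correlation with the observed means, for fits computed on the same data.
#'
#' @param ... `causal_fit` objects, or a single list of them.
#' @return data.frame, one row per fit.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "causal_fit"))
    fits <- fits[[1]]
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1),
                                          "causal_fit")))
  key0 <- question_key(fits[[1]]$means$round, fits[[1]]$means$cause)
  for (f in fits[-1]) {
    if (!identical(sort(question_key(f$means$round, f$means$cause)),
                   sort(key0)))
      stop("fits were not computed on identical data")
  }
  do.call(rbind, lapply(fits, function(f) data.frame(
    model = f$model, s = f$par[["s"]], w = f$par[["w"]],
    gamma = f$par[["gamma"]], sigma = f$par[["sigma"]],
    loglik = f$loglik, npar = f$npar, aic = f$aic, bic = f$bic,
    correlation = f$correlation, stringsAsFactors = FALSE)))
}

## ---- S3 methods -------------------------------------------------------------

#' @export
print.causal_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Causal-selection model fit: %s (%d questions)\n",
              x$model, x$nobs))
  par <- x$par[!is.na(x$par)]
  cat("  ", paste(sprintf("%s = %.*g", names(par), digits, par),
                  collapse = ", "), "\n", sep = "")
  cat(sprintf("  logLik = %.2f, AIC = %.2f, BIC = %.2f, cor = %.3f\n",
              x$loglik, x$aic, x$bic, x$correlation))
  invisible(x)
}

#' @export
summary.causal_fit <- function(object, ...) {
  res <- data.frame(round = object$means$round, cause = object$means$cause,
                    observed_mean = object$means$mean,
                    raw_score = as.numeric(object$raw),
                    fitted = as.numeric(object$fitted),
                    residual = as.numeric(object$fitted - object$observed),
                    stringsAsFactors = FALSE)
  structure(list(fit = object, table = res), class = "summary.causal_fit")
}

#' @export
print.summary.causal_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-question fit (fitted and residual on the rescaled [0,1] scale):\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.causal_fit <- function(object, ...) object$par[!is.na(object$par)]

#' @export
logLik.causal_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$nobs,
            class = "logLik")
}

#' @export
fitted.causal_fit <- function(object, ...) {
  stats::setNames(object$fitted,
                  question_key(object$means$round, object$means$cause))
}

#' @export
residuals.causal_fit <- function(object, ...) {
  stats::setNames(object$fitted - object$observed,
                  question_key(object$means$round, object$means$cause))
}

#' Predicted ratings from a fitted model
#'
#' @param object a `causal_fit`.
#' @param ... unused.
#' @return data.frame with the scaled prediction (on \[0,1\]) and its
#'   affine image on the 1-9 rating scale for each fitted question.
#' @export
predict.causal_fit <- function(object, ...) {
  data.frame(round = object$means$round, cause = object$means$cause,
             prediction = as.numeric(object$fitted),
             rating_scale = 1 + 8 * as.numeric(object$fitted),
             stringsAsFactors = FALSE)
}

#' @export
plot.causal_fit <- function(x, ...) {
  plot(x$fitted, x$observed,
       xlab = "fitted (scaled model prediction)",
       ylab = "observed mean (rescaled)",
       main = sprintf("%s fit: r = %.2f", x$model, x$correlation), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
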