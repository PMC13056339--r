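## Means data.frame directly from noise-free model predictions.
exact_means <- function(spec, model, s, w = 0, gamma = 1) {
  tab <- prediction_table(spec, model, s = s, w = w, gamma = gamma)
  data.frame(round = tab$round, cause = tab$cause,
             mean = 1 + 8 * tab$scaled, n = 1L, stringsAsFactors = FALSE)
}

test_that("prediction scaling is a clipped power transform", {
  expect_equal(scale_prediction(1.0, 0.26), 1.0)
  expect_equal(scale_prediction(0.25, 0.5), 0.5)
  expect_equal(scale_prediction(-0.2, 0.26), 0)
  expect_equal(scale_prediction(c(0, 1, 0.5), 2), c(0, 1, 0.25))
})

test_that("zero-noise data with the truth on the grid are recovered exactly", {
  e1 <- experiment1()
  means <- exact_means(e1, "cesm", s = 0.5, gamma = 1)
  fit <- fit_causal_model(means, e1, "cesm",
                          s_grid = seq(0, 1, 0.1),
                          gamma_grid = c(0.5, 1, 2))
  expect_equal(unname(coef(fit)[c("s", "gamma")]), c(0.5, 1))
  expect_lt(fit$par[["sigma"]], 1e-9)
})

test_that("noisy Exp-1-shaped means recover the generating stability", {
  e1 <- experiment1()
  tab <- prediction_table(e1, "cesm", s = 0.89, gamma = 0.26)
  set.seed(2024)
  s_hat <- replicate(20, {
    noisy <- tab$scaled + rnorm(nrow(tab), 0, 0.03)
    means <- data.frame(round = tab$round, cause = tab$cause,
                        mean = pmin(9, pmax(1, 1 + 8 * noisy)))
    fit <- fit_causal_model(means, e1, "cesm")
    fit$par[["s"]]
  })
  expect_lte(median(abs(s_hat - 0.89)), 0.1)
})

test_that("the generating model dominates the constant baseline in likelihood", {
  e1 <- experiment1()
  tab <- prediction_table(e1, "cesm", s = 0.89, gamma = 0.26)
  set.seed(7)
  noisy <- tab$scaled + rnorm(nrow(tab), 0, 0.03)
  means <- data.frame(round = tab$round, cause = tab$cause,
                      mean = pmin(9, pmax(1, 1 + 8 * noisy)))
  fit <- fit_causal_model(means, e1, "cesm")
  base <- constant_baseline_fit(means)
  expect_gt(fit$loglik, base$loglik)
  expect_lt(fit$bic, base$bic)
  expect_equal(base$correlation, 0)
  expect_equal(base$npar, 2L)
  ## all means equal to 5: zero residuals at gamma = 1 (0.5^1 = (5-1)/8)
  flat <- data.frame(round = "win", cause = c("a", "b", "c"),
                     mean = c(5, 5, 5))
  bf <- constant_baseline_fit(flat, gamma_grid = c(0.5, 1, 2))
  expect_equal(bf$par[["gamma"]], 1)
  expect_lt(bf$par[["sigma"]], 1e-9)
})

test_that("grid_fit is exhaustive, order-invariant, and breaks ties low", {
  means <- data.frame(round = "r", cause = c("A", "B", "A&B"),
                      mean = c(3, 5, 7))
  fn <- function(s, w = 0) {
    stats::setNames(c(0.2 + 0.3 * s, 0.5, 0.9 - 0.2 * s),
                    c("r:A", "r:B", "r:A&B"))
  }
  s_grid <- seq(0, 1, 0.25); gamma_grid <- c(0.5, 1, 2)
  fit <- grid_fit(fn, means, s_grid = s_grid, gamma_grid = gamma_grid)
  ## brute-force check of exhaustiveness with the same profiled likelihood
  obs <- (means$mean - 1) / 8
  for (s in s_grid) for (g in gamma_grid) {
    resid <- pmax(fn(s), 0)^g - obs
    ll <- -length(obs) / 2 * (log(2 * pi * mean(resid^2)) + 1)
    expect_gte(fit$loglik, ll - 1e-10)
  }
  ## shuffling the question rows changes nothing
  fit2 <- grid_fit(fn, means[c(3, 1, 2), ], s_grid = s_grid,
                   gamma_grid = gamma_grid)
  expect_equal(fit2$loglik, fit$loglik)
  expect_equal(coef(fit2), coef(fit))
  ## a prediction function ignoring s ties across the whole s grid: the
  ## smallest s wins, while gamma is still identified by the data
  cfn <- function(s, w = 0) stats::setNames(rep(0.5, 3), c("r:A", "r:B", "r:A&B"))
  tie <- grid_fit(cfn, means, s_grid = s_grid, gamma_grid = gamma_grid)
  expect_equal(tie$par[["s"]], 0)
  expect_equal(tie$par[["gamma"]], 1)  # 0.5^1 minimizes the residuals
  ## fully degenerate (score 1 is invariant to gamma): every grid point
  ## fits perfectly, and the smallest (s, gamma) is selected
  one <- function(s, w = 0) stats::setNames(rep(1, 3), c("r:A", "r:B", "r:A&B"))
  flat <- data.frame(round = "r", cause = c("A", "B", "A&B"), mean = c(9, 9, 9))
  tie2 <- grid_fit(one, flat, s_grid = s_grid, gamma_grid = gamma_grid)
  expect_equal(tie2$par[["s"]], 0)
  expect_equal(tie2$par[["gamma"]], 0.5)
})

test_that("the linear-combination baseline averages singular means", {
  means <- data.frame(round = "r",
                      cause = c("A", "B", "C", "A&B", "A&C", "B&C"),
                      mean = c(4, 6, 8, 2, 2, 2))
  pred <- linear_combination_baseline(means)
  expect_equal(pred$prediction[pred$cause == "A&B"], 5)
  expect_equal(pred$prediction[pred$cause == "A&C"], 6)
  expect_equal(pred$prediction[pred$cause == "B&C"], 7)
  ## idempotence: equal singulars map to themselves
  m2 <- data.frame(round = "r", cause = c("A", "B", "A&B"), mean = c(6, 6, 1))
  expect_equal(linear_combination_baseline(m2)$prediction, 6)
  ## permutation-equivariance under variable relabeling
  perm <- data.frame(round = "r",
                     cause = c("A", "B", "C", "A&B", "A&C", "B&C"),
                     mean = c(8, 6, 4, 2, 2, 2))
  pp <- linear_combination_baseline(perm)
  expect_equal(pp$prediction[pp$cause == "B&C"],
               pred$prediction[pred$cause == "A&B"])
  expect_error(linear_combination_baseline(
    data.frame(round = "r", cause = c("A", "A&B"), mean = c(4, 5))),
    "missing singular")
})

test_that("model comparison reports consistent information criteria", {
  e1 <- experiment1()
  means <- exact_means(e1, "cesm", s = 0.6, gamma = 0.5)
  fit <- fit_causal_model(means, e1, "cesm", s_grid = seq(0, 1, 0.2),
                          gamma_grid = c(0.5, 1))
  tab1 <- compare_models(fit)
  expect_equal(nrow(tab1), 1)
  expect_equal(tab1$aic, 2 * fit$npar - 2 * fit$loglik)
  expect_equal(tab1$bic, fit$npar * log(fit$nobs) - 2 * fit$loglik)

  base <- constant_baseline_fit(means)
  tab <- compare_models(fit, base)
  expect_equal(nrow(tab), 2)
  ## equal parameter count, lower loglik => higher BIC
  base2 <- constant_baseline_fit(means, gamma_grid = c(0.77))
  expect_lte(base2$loglik, base$loglik)
  expect_gte(base2$bic, base$bic)

  other <- fit_causal_model(means[c(2, 1, 3:7), ], e1, "cesm",
                            s_grid = c(0.5), gamma_grid = c(1))
  expect_silent(compare_models(fit, other))
  mism <- fit_causal_model(means[1:6, ], e1, "cesm", s_grid = c(0.5),
                           gamma_grid = c(1))
  expect_error(compare_models(fit, mism), "identical data")
})

test_that("the free-w model beats the fixed-w model on w-generated loss data", {
  spec <- experiment2(c("triple_negative", "overdetermined_negative"))
  means <- exact_means(spec, "cesm", s = 0.21, w = 0.77, gamma = 0.41)
  s_grid <- c(0.1, 0.21, 0.3); gamma_grid <- c(0.2, 0.41, 0.8)
  free_w <- fit_causal_model(means, spec, "cesm", s_grid = s_grid,
                             w_grid = seq(0, 1, 0.07), gamma_grid = gamma_grid)
  no_w <- fit_causal_model(means, spec, "cesm", s_grid = s_grid,
                           w_grid = 0, gamma_grid = gamma_grid)
  expect_equal(no_w$npar, 3L)
  expect_equal(free_w$npar, 4L)
  expect_gt(free_w$loglik, no_w$loglik)
  expect_lt(free_w$bic, no_w$bic)
  expect_equal(no_w$par[["w"]], 0)
})

test_that("fit_causal_model validates its inputs", {
  e1 <- experiment1()
  bad <- data.frame(round = "win", cause = "low", mean = 11)
  expect_error(fit_causal_model(bad, e1, "cesm"), "1-9")
  off <- data.frame(round = "nope", cause = "low", mean = 5)
  expect_error(fit_causal_model(off, e1, "cesm"), "absent from the spec")
  unknown_q <- data.frame(round = "win", cause = "low&nothere", mean = 5)
  expect_error(fit_causal_model(unknown_q, e1, "cesm"), "missing")
})
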