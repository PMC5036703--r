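test_that("WAIC matches hand computation and degenerates correctly", {
  tab <- tiny_table(n_access = 0)
  # two cells, two draws, hand-listed pointwise log-likelihoods
  ll <- matrix(c(-1, -1.5, -2, -1), 2, 2)
  pars <- matrix(0, 2, 1, dimnames = list(NULL, "gamma_intercept"))
  fit <- fake_fit(pars,
    f = matrix(0, 2, 3), u = matrix(0, 2, 3), table = tab,
    pointwise = list(outcome = ll)
  )
  w <- waic(fit, "outcome")
  expect_equal(w$lppd, -2.598956, tolerance = 1e-6)
  expect_equal(w$p_waic, 0.625, tolerance = 1e-9)
  expect_equal(w$waic, 6.447911, tolerance = 1e-6)

  # single draw: p_waic = 0 and WAIC = -2 * total loglik
  fit1 <- fake_fit(pars[1, , drop = FALSE],
    f = matrix(0, 1, 3), u = matrix(0, 1, 3), table = tab,
    pointwise = list(outcome = ll[1, , drop = FALSE])
  )
  w1 <- waic(fit1, "outcome")
  expect_equal(w1$p_waic, 0)
  expect_equal(w1$waic, -2 * sum(ll[1, ]))
  expect_error(waic(fit1, "access"), "not fitted")
})

test_that("WAIC is additive over disjoint cell partitions", {
  set.seed(5)
  ll <- matrix(rnorm(60, -2, 0.3), 10, 6)
  tab <- tiny_table(n_access = 0)
  pars <- matrix(0, 10, 1, dimnames = list(NULL, "gamma_intercept"))
  mk <- function(cells) {
    fake_fit(pars,
      f = matrix(0, 10, 3), u = matrix(0, 10, 3), table = tab,
      pointwise = list(outcome = ll[, cells, drop = FALSE])
    )
  }
  whole <- waic(mk(1:6), "outcome")
  left <- waic(mk(1:2), "outcome")
  right <- waic(mk(3:6), "outcome")
  expect_equal(whole$waic, left$waic + right$waic, tolerance = 1e-9)
})

test_that("sign probabilities and Bayes factors follow the odds identity", {
  expect_equal(round(marginal_bayes_factor(0.918), 1), 11.2)
  expect_equal(marginal_bayes_factor(0.5), 1)
  expect_equal(marginal_bayes_factor(0.9), 9, tolerance = 1e-12)
  # strictly increasing in p
  ps <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(marginal_bayes_factor(ps)) > 0))
  expect_error(marginal_bayes_factor(1.2), "lie in")
  expect_warning(marginal_bayes_factor(1), "Monte-Carlo")

  tab <- tiny_table(n_access = 0)
  pars <- matrix(c(-0.5, -0.1, -0.2, 0.3, -0.3, 0.4), 3, 2,
    dimnames = list(NULL, c("gamma_intercept", "gamma_quality"))
  )
  fit <- fake_fit(pars, f = matrix(0, 3, 3), u = matrix(0, 3, 3), table = tab)
  expect_equal(sign_probability(fit, "gamma_intercept")$prob_negative, 1)
  sp <- sign_probability(fit, "gamma_quality")
  expect_equal(sp$prob_negative + sp$prob_positive, 1)
  expect_error(sign_probability(fit, "nope"), "not sampled")
})

test_that("factor-risk curves reproduce flat and linear relations", {
  tab <- tiny_table(n_access = 0)
  tab <- compute_expected_counts(tab)
  I <- 3
  # single draw; u chosen so that nu is exactly linear in the score
  f <- seq(-1, 1, length.out = I)
  a <- 2
  b <- 0.5
  g0 <- 0.1
  g1 <- -0.3
  u <- log(a + b * f) - g0 - g1 * f
  pars <- matrix(c(g0, g1), 1, 2,
    dimnames = list(NULL, c("gamma_intercept", "gamma_quality"))
  )
  fit <- fake_fit(pars,
    f = matrix(f, 1, I), u = matrix(u, 1, I), table = tab
  )
  curve <- factor_risk_curve(fit, "quality")
  expect_equal(curve$relative_risk, a + b * curve$score, tolerance = 1e-9)
  expect_equal(curve$smooth, a + b * curve$score, tolerance = 1e-6)

  # constant risk: flat smooth
  u_flat <- 0 - g0 - g1 * f
  fit_flat <- fake_fit(pars,
    f = matrix(f, 1, I), u = matrix(u_flat, 1, I), table = tab
  )
  curve_flat <- factor_risk_curve(fit_flat, "quality")
  expect_equal(diff(range(curve_flat$smooth)), 0, tolerance = 1e-9)
  expect_error(factor_risk_curve(fit_flat, "poor_access"), "not part")
})

test_that("higher latent quality is associated with lower fitted risk", {
  fit <- quick_fit()
  curve <- factor_risk_curve(fit, "quality")
  expect_lt(stats::cor(curve$score, curve$smooth), 0)
})

test_that("posterior predictive checks detect gross misfit but pass the fitted data", {
  fit <- quick_fit()
  set.seed(31)
  p_bad <- posterior_predictive_check(
    fit, "admissions",
    observed = fit$table$admissions * 10L
  )
  expect_lt(p_bad, 0.05)
  set.seed(31)
  p_ok <- posterior_predictive_check(fit, "admissions")
  expect_gt(p_ok, 0.01)
  expect_lt(p_ok, 0.99)
  expect_error(posterior_predictive_check(fit, "q_9"), "unknown variable")
})

test_that("the criticism report covers every observed variable", {
  fit <- quick_fit()
  rep <- fit_report(fit, seed = 2)
  expect_identical(rep$ppc$variable, c("admissions", paste0("z_", 1:4), paste0("w_", 1:4)))
  expect_true(all(rep$ppc$p_value >= 0 & rep$ppc$p_value <= 1))
  expect_identical(rep$waic$component, c("outcome", "quality", "access"))
  expect_true(all(is.finite(rep$waic$waic)))
  expect_true(all(c("gamma_quality", "beta_depr_access") %in% rep$coefficients$term))
  expect_output(print(rep), "WAIC by component")
})
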