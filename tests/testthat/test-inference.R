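test_that("chains are deterministic given the seed", {
  tab <- simulate_practice_data(generator_config(n_practice = 10, seed = 2))
  f1 <- fit_admissions_sem(tab, model_config(3),
    chains = 1, iterations = 300, burn_in = 100, thin = 2, seed = 9
  )
  f2 <- fit_admissions_sem(tab, model_config(3),
    chains = 1, iterations = 300, burn_in = 100, thin = 2, seed = 9
  )
  expect_identical(f1$chains[[1]]$pars, f2$chains[[1]]$pars)
  expect_identical(f1$chains[[1]]$f, f2$chains[[1]]$f)
  f3 <- fit_admissions_sem(tab, model_config(3),
    chains = 1, iterations = 300, burn_in = 100, thin = 2, seed = 10
  )
  expect_false(identical(f1$chains[[1]]$pars, f3$chains[[1]]$pars))
})

test_that("the shared-overdispersion variant keeps one sd per block", {
  tab <- simulate_practice_data(generator_config(n_practice = 10, seed = 2))
  fit <- fit_admissions_sem(
    tab, model_config(3, shared_overdispersion = TRUE),
    chains = 1, iterations = 400, burn_in = 200, thin = 2, seed = 1
  )
  draws <- caresem:::stacked_pars(fit)
  sig <- draws[, sprintf("sigma[%d]", 1:4)]
  expect_equal(apply(sig, 1, function(x) diff(range(x))), rep(0, nrow(sig)))
  expect_gt(stats::sd(sig[, 1]), 0)
})

test_that("initialization moment-matches the data and survives boundaries", {
  tab <- tiny_table()
  cfg <- model_config(3, n_quality = 2, n_access = 2)
  st <- initialize_chain(tab, cfg, seed = 1)
  mats <- indicator_matrices(tab)
  expect_equal(
    st$delta,
    stats::qlogis((colSums(mats$Z) + 0.5) / (colSums(mats$N) + 1))
  )
  # an all-zero survey column still yields finite intercepts
  tab0 <- tiny_table()
  tab0$w_2 <- c(0L, 0L, 0L)
  st0 <- initialize_chain(tab0, cfg, seed = 1)
  expect_true(all(is.finite(st0$eta)))
  # jitter is seed-dependent
  st2 <- initialize_chain(tab, cfg, seed = 2)
  expect_false(identical(st$f, st2$f))
  expect_identical(st$delta, st2$delta)
})

test_that("prior-only sampling recovers the prior moments", {
  tab <- simulate_practice_data(generator_config(n_practice = 8, seed = 3))
  cfg <- model_config(1,
    n_quality = 4, n_access = 0,
    coef_prior_sd = 1, prior_only = TRUE
  )
  fit <- fit_admissions_sem(tab, cfg,
    chains = 2, iterations = 6000, burn_in = 2000, thin = 2, seed = 4
  )
  draws <- caresem:::stacked_pars(fit)
  g1 <- draws[, "gamma_quality"]
  ess <- convergence_report(fit)
  ess_g1 <- ess$ess[ess$term == "gamma_quality"]
  # Normal(0, 1) prior: mean 0, sd 1, within 3 Monte-Carlo standard errors
  expect_lt(abs(mean(g1)), 3 / sqrt(ess_g1) + 0.02)
  expect_equal(stats::sd(g1), 1, tolerance = 0.15)
  # Half-Normal(0, 1) prior on the outcome overdispersion sd: mean 0.798
  expect_equal(mean(draws[, "alpha"]), sqrt(2 / pi), tolerance = 0.15)
  expect_true(all(draws[, "alpha"] >= 0))
})

test_that("posterior summaries match a sort-based quantile oracle", {
  fit <- quick_fit()
  summ <- posterior_summaries(fit)
  anchor <- summ[summ$term == "lambda[1]", ]
  expect_equal(anchor$mean, 1)
  expect_equal(anchor$sd, 0)
  expect_equal(anchor$conf.low, 1)
  expect_equal(anchor$conf.high, 1)

  draws <- sort(caresem:::stacked_pars(fit)[, "gamma_deprivation"])
  n <- length(draws)
  interp <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    draws[lo] + (h - lo) * (draws[min(lo + 1, n)] - draws[lo])
  }
  row <- summ[summ$term == "gamma_deprivation", ]
  expect_equal(row$conf.low, interp(0.025), tolerance = 1e-12)
  expect_equal(row$conf.high, interp(0.975), tolerance = 1e-12)
  expect_equal(row$mean, mean(draws), tolerance = 1e-12)
  # near-symmetric posterior: mean close to median
  expect_equal(row$mean, interp(0.5), tolerance = 5 * row$sd / sqrt(n) + 0.01)
})

test_that("convergence diagnostics behave on white-noise and AR(1) oracles", {
  make_fake <- function(chain_draws) {
    structure(
      list(chains = lapply(chain_draws, function(x) {
        list(pars = matrix(x, ncol = 1, dimnames = list(NULL, "theta")))
      })),
      class = "sem_fit"
    )
  }
  set.seed(11)
  n <- 4000
  wn <- make_fake(list(rnorm(n), rnorm(n)))
  rep_wn <- convergence_report(wn)
  expect_lt(abs(rep_wn$rhat - 1), 0.01)
  expect_gt(rep_wn$ess, 0.7 * 2 * n)
  expect_false(rep_wn$flagged)

  # AR(1) with phi = 0.9: ESS/n -> (1 - phi)/(1 + phi) = 1/19
  phi <- 0.9
  ar <- replicate(2, as.vector(stats::arima.sim(list(ar = phi), n)), simplify = FALSE)
  rep_ar <- convergence_report(make_fake(ar))
  expect_lt(rep_ar$ess, 2 * n / 8)
  expect_gt(rep_ar$ess, 2 * n / 60)

  # constant chains: flagged, not crashing
  cst <- make_fake(list(rep(1, 100), rep(1, 100)))
  rep_cst <- convergence_report(cst)
  expect_true(is.na(rep_cst$rhat))
  expect_true(rep_cst$flagged)
})

test_that("tidy and glance return the documented shapes", {
  fit <- quick_fit()
  td <- tidy(fit)
  expect_true(all(c(
    "term", "estimate", "std.error", "conf.low", "conf.high",
    "prob_negative", "prob_positive"
  ) %in% names(td)))
  expect_equal(td$prob_negative + td$prob_positive,
    rep(1, nrow(td)),
    tolerance = 1e-9
  )
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(all(is.finite(c(gl$waic_outcome, gl$waic_quality, gl$waic_access))))
  sc <- latent_scores(fit)
  expect_identical(nrow(sc), nrow(fit$table))
  expect_true(all(c("quality_mean", "poor_access_mean") %in% names(sc)))
})
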