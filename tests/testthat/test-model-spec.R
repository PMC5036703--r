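test_that("likelihood kernels reproduce closed-form values and stay finite", {
  # direct factorial evaluations, frozen
  expect_equal(
    loglik_quality(matrix(5), matrix(10), delta = 0, lambda = 1, f = 0)[1, 1],
    -1.402043,
    tolerance = 1e-6
  )
  expect_equal(
    loglik_access(matrix(0), matrix(10),
      eta = stats::qlogis(0.1), kappa = 1, g = 0
    )[1, 1],
    -1.053605,
    tolerance = 1e-6
  )
  expect_equal(loglik_outcome(0, 1, 1), -1)
  expect_equal(loglik_outcome(3, 1, 3), -1.495923, tolerance = 1e-6)

  # saturation: Z = N with growing linear predictor pushes loglik to 0
  lls <- vapply(
    c(2, 5, 10, 20),
    function(d) loglik_quality(matrix(10), matrix(10), d, 1, 0)[1, 1],
    numeric(1)
  )
  expect_true(all(diff(lls) > 0))
  expect_gt(lls[4], -1e-6)
  # boundary counts finite at extreme predictors
  expect_true(is.finite(loglik_quality(matrix(0), matrix(50), 30, 1, 0)[1, 1]))
  expect_true(is.finite(loglik_quality(matrix(50), matrix(50), -30, 1, 0)[1, 1]))

  # binomial symmetry: flipping the predictor sign swaps successes/failures
  expect_equal(
    loglik_access(matrix(3), matrix(10), 0.7, 1, 0)[1, 1],
    loglik_access(matrix(7), matrix(10), -0.7, 1, 0)[1, 1]
  )
  # access and quality kernels agree under renaming
  expect_equal(
    loglik_access(matrix(4), matrix(9), 0.3, 1.2, 0.5),
    loglik_quality(matrix(4), matrix(9), 0.3, 1.2, 0.5)
  )
  expect_error(loglik_quality(matrix(12), matrix(10), 0, 1, 0), "Z <= N")
  expect_error(loglik_outcome(-1, 1, 1), "non-negative")
})

test_that("likelihood at the saturated relative risks bounds any other", {
  set.seed(3)
  y <- rpois(20, 5)
  e <- runif(20, 2, 8)
  nu_hat <- pmax(y, 1e-8) / e
  best <- sum(loglik_outcome(y, e, nu_hat))
  for (r in 1:20) {
    nu <- nu_hat * exp(rnorm(20, 0, 0.3))
    expect_lte(sum(loglik_outcome(y, e, nu)), best)
  }
})

test_that("the linear predictor composes model-specific terms", {
  p <- default_parameters(1)
  lat0 <- list(f = rep(0, 2), u = rep(0, 2))
  expect_equal(
    linear_predictor_nu(p, lat0, model = 1),
    rep(exp(0.02), 2)
  )
  # one latent unit of quality changes risk by exp(gamma_quality)
  lat1 <- list(f = c(0, 1), u = c(0, 0))
  nu <- linear_predictor_nu(p, lat1, model = 1)
  expect_equal(nu[2] / nu[1], exp(-0.25), tolerance = 1e-12)

  # model 3: one unit of poor access is a risk ratio exp(0.18) = 1.1972
  p3 <- default_parameters(3)
  covs <- list(deprivation = c(0, 0), morbidity = c(0, 0))
  lat3 <- list(f = c(0, 0), g = c(0, 1), u = c(0, 0))
  nu3 <- linear_predictor_nu(p3, lat3, covs, model = 3)
  expect_equal(nu3[2] / nu3[1], 1.197217, tolerance = 1e-6)

  # zero everything: reference risk 1
  pz <- p3
  pz$gamma[] <- 0
  expect_equal(
    linear_predictor_nu(pz, list(f = 0, g = 0, u = 0),
      list(deprivation = 0, morbidity = 0),
      model = 3
    ),
    1
  )
  expect_error(
    linear_predictor_nu(p3, list(f = c(0, 0), u = c(0, 0)), covs, model = 3),
    "poor-access"
  )
})

test_that("model nesting holds for the outcome likelihood", {
  tab <- simulate_practice_data(generator_config(n_practice = 12, seed = 4))
  p3 <- default_parameters(3)
  p3$gamma[["poor_access"]] <- 0
  p2 <- default_parameters(2)
  p2$gamma <- c(
    intercept = p3$gamma[["intercept"]], quality = p3$gamma[["quality"]],
    deprivation = p3$gamma[["deprivation"]], morbidity = p3$gamma[["morbidity"]]
  )
  set.seed(1)
  f <- rnorm(12)
  g <- rnorm(12)
  u <- rnorm(12, 0, 0.1)
  nu3 <- linear_predictor_nu(p3, list(f = f, g = g, u = u), tab, model = 3)
  nu2 <- linear_predictor_nu(p2, list(f = f, u = u), tab, model = 2)
  expect_equal(
    loglik_outcome(tab$admissions, tab$expected, nu3),
    loglik_outcome(tab$admissions, tab$expected, nu2)
  )
  # model 2 with its covariate terms zeroed reproduces model 1
  p2z <- p2
  p2z$gamma[c("deprivation", "morbidity")] <- 0
  p1 <- default_parameters(1)
  p1$gamma <- p2$gamma[c("intercept", "quality")]
  expect_equal(
    linear_predictor_nu(p2z, list(f = f, u = u), tab, model = 2),
    linear_predictor_nu(p1, list(f = f, u = u), tab, model = 1)
  )
})

test_that("anchoring the first loading removes scale non-identifiability", {
  tab <- simulate_practice_data(generator_config(n_practice = 12, seed = 4))
  mats <- indicator_matrices(tab)
  p <- default_parameters(3)
  set.seed(2)
  f <- rnorm(12, 0, 0.5)
  base <- sum(loglik_quality(mats$Z, mats$N, p$delta, p$lambda, f))
  # rescale the latent scale and divide free loadings: with lambda[1]
  # anchored the transformed loading vector is not a valid reparameterization
  # and the likelihood must change
  cc <- 2
  lam_scaled <- c(1, p$lambda[-1] / cc)
  scaled <- sum(loglik_quality(mats$Z, mats$N, p$delta, lam_scaled, f * cc))
  expect_gt(abs(scaled - base), 1)
})

test_that("the prior is sign-neutral on coefficients and proper on scales", {
  cfg <- model_config(3)
  p <- default_parameters(3)
  pm <- p
  pm$gamma[["quality"]] <- -p$gamma[["quality"]]
  pm$beta[["depr_access"]] <- -p$beta[["depr_access"]]
  expect_equal(log_prior(p, cfg), log_prior(pm, cfg))

  bad <- p
  bad$alpha <- -0.1
  expect_identical(log_prior(bad, cfg), -Inf)
  bad2 <- p
  bad2$rho <- 1.2
  expect_identical(log_prior(bad2, cfg), -Inf)
  expect_true(is.finite(log_prior(p, cfg)))
})

test_that("identification constraints are enforced at construction", {
  expect_error(
    sem_params(
      gamma = c(intercept = 0, quality = 0), alpha = 0.1,
      lambda = c(2, 1), delta = c(0, 0), sigma = c(0.1, 0.1)
    ),
    "lambda"
  )
  expect_error(
    {
      p <- default_parameters(3)
      p$rho <- -1
      caresem:::validate_sem_params(p)
    },
    "rho"
  )
})

test_that("pointwise log-likelihood cells sum to the component totals", {
  tab <- simulate_practice_data(generator_config(n_practice = 10, seed = 6))
  truth <- simulation_truth(tab)
  p <- truth$params
  lat <- list(
    f = truth$latents$f, g = truth$latents$g, u = truth$latents$u,
    eps = truth$eps, e = truth$e
  )
  pw <- pointwise_loglik(p, lat, tab, model = 3)
  expect_identical(
    sum(pw$component == "outcome"), 10L
  )
  expect_identical(sum(pw$component == "quality"), 40L)
  expect_identical(sum(pw$component == "access"), 40L)

  mats <- indicator_matrices(tab)
  tot_q <- sum(loglik_quality(mats$Z, mats$N, p$delta, p$lambda, lat$f, lat$eps))
  expect_equal(sum(pw$loglik[pw$component == "quality"]), tot_q, tolerance = 1e-9)
  nu <- linear_predictor_nu(p, lat, tab, 3)
  tot_y <- sum(loglik_outcome(tab$admissions, tab$expected, nu))
  expect_equal(sum(pw$loglik[pw$component == "outcome"]), tot_y, tolerance = 1e-9)

  # spot-check 5 random cells against scalar dbinom/dpois
  set.seed(8)
  qcells <- pw[pw$component == "quality", ]
  for (idx in sample(nrow(qcells), 5)) {
    row <- qcells[idx, ]
    i <- match(row$practice_id, tab$practice_id)
    j <- row$indicator
    pij <- stats::plogis(p$delta[j] + p$lambda[j] * lat$f[i] + lat$eps[i, j])
    expect_equal(
      row$loglik,
      stats::dbinom(mats$Z[i, j], mats$N[i, j], pij, log = TRUE),
      tolerance = 1e-9
    )
  }
})
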