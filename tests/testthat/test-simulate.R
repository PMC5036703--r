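test_that("generation is deterministic given config and seed", {
  a <- simulate_practice_data(generator_config(n_practice = 20, seed = 77))
  b <- simulate_practice_data(generator_config(n_practice = 20, seed = 77))
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- simulate_practice_data(generator_config(n_practice = 20, seed = 78))
  expect_false(identical(a$admissions, c$admissions))
})

test_that("latent factors reproduce the configured correlation structure", {
  # independence case
  p0 <- default_parameters(3)
  p0$rho <- 0
  p0$beta[] <- 0
  cfg <- generator_config(n_practice = 50000, params = p0, seed = 1)
  set.seed(1)
  covs <- simulate_covariates(cfg)
  lat <- simulate_latents(cfg, covs)
  expect_lt(abs(stats::cor(lat$f, lat$g)), 0.02)
  expect_equal(stats::sd(lat$f), 0.5, tolerance = 0.02)
  expect_equal(stats::sd(lat$g), 0.8, tolerance = 0.02)

  # study correlation, net of shared covariate-driven means
  p1 <- default_parameters(3)
  p1$beta[] <- 0
  cfg1 <- generator_config(n_practice = 50000, params = p1, seed = 2)
  set.seed(2)
  lat1 <- simulate_latents(cfg1, simulate_covariates(cfg1))
  expect_lt(abs(stats::cor(lat1$f, lat1$g) - (-0.38)), 0.01)

  # covariate-driven means: regression of g on deprivation recovers beta
  p2 <- default_parameters(3)
  cfg2 <- generator_config(n_practice = 50000, params = p2, seed = 3)
  set.seed(3)
  covs2 <- simulate_covariates(cfg2)
  lat2 <- simulate_latents(cfg2, covs2)
  co <- stats::coef(stats::lm(lat2$g ~ covs2$deprivation + covs2$gp_rate + covs2$list_size))
  expect_lt(abs(co[[2]] - 0.45), 0.015)
  expect_lt(abs(co[[3]] - (-0.37)), 0.015)
})

test_that("student-t factors are heavier-tailed than normal factors", {
  kurt <- function(x) mean((x - mean(x))^4) / stats::var(x)^2
  p <- default_parameters(3)
  p$beta[] <- 0
  cfg_n <- generator_config(n_practice = 50000, params = p, seed = 4)
  cfg_t <- generator_config(
    n_practice = 50000, params = p, seed = 4, model = 4,
    factor_family = "student_t"
  )
  set.seed(4)
  lat_n <- simulate_latents(cfg_n, simulate_covariates(cfg_n))
  set.seed(4)
  lat_t <- simulate_latents(cfg_t, simulate_covariates(cfg_t))
  expect_equal(kurt(lat_n$f), 3, tolerance = 0.2)
  expect_gt(kurt(lat_t$f), kurt(lat_n$f) + 1)
  expect_true(all(lat_t$omega > 0))
})

test_that("indicator generation matches configured rates and overdispersion", {
  # zero loadings, zero noise, zero intercepts: pooled rate 1/2
  p <- default_parameters(3)
  p$lambda <- c(1, rep(0, 3))
  p$kappa <- c(1, rep(0, 3))
  p$sigma[] <- 0
  p$tau[] <- 0
  p$delta[] <- 0
  p$psi <- c(1e-5, 1e-5)
  p$beta[] <- 0
  cfg <- generator_config(n_practice = 2000, params = p, seed = 5)
  set.seed(5)
  covs <- simulate_covariates(cfg)
  lat <- simulate_latents(cfg, covs)
  ind <- simulate_indicators(cfg, lat)
  expect_equal(sum(ind$Z[, 2]) / sum(ind$N[, 2]), 0.5, tolerance = 0.01)
  expect_true(all(ind$Z >= 0 & ind$Z <= ind$N))
  expect_true(all(ind$W >= 0 & ind$W <= ind$V))

  # logit-normal overdispersion inflates the chi-square dispersion
  # statistic relative to the sigma = 0 binomial oracle
  dispersion <- function(z, n) {
    phat <- sum(z) / sum(n)
    sum((z - n * phat)^2 / (n * phat * (1 - phat))) / (length(z) - 1)
  }
  p_od <- p
  p_od$sigma[] <- 0.3
  cfg_od <- generator_config(n_practice = 2000, params = p_od, seed = 6)
  set.seed(6)
  ind_od <- simulate_indicators(cfg_od, lat)
  expect_lt(dispersion(ind$Z[, 2], ind$N[, 2]), 1.2)
  expect_gt(dispersion(ind_od$Z[, 2], ind_od$N[, 2]), 2)
})

test_that("outcome generation matches closed-form expectations", {
  # null model: Y/E centred on 1
  p <- default_parameters(3)
  p$gamma[] <- 0
  p$alpha <- 0
  cfg <- generator_config(n_practice = 5000, params = p, seed = 7)
  tab <- simulate_practice_data(cfg)
  truth <- simulation_truth(tab)
  expect_equal(mean(tab$admissions / truth$exposure), 1, tolerance = 0.01)

  # log-scale random effect inflates the variance of log(Y/E)
  p_a <- default_parameters(3)
  p_a$gamma[] <- 0
  p_a$alpha <- 0.3
  cfg_a <- generator_config(
    n_practice = 5000, params = p_a, seed = 7, mean_expected = 200
  )
  tab_a <- simulate_practice_data(cfg_a)
  v0 <- stats::var(log(pmax(tab$admissions, 0.5) / simulation_truth(tab)$exposure))
  v1 <- stats::var(log(pmax(tab_a$admissions, 0.5) / simulation_truth(tab_a)$exposure))
  expect_gt(v1, v0)
})

test_that("simulated crosswalks are row-stochastic with the study dimensions", {
  cw <- simulate_crosswalk(n_area = 260, n_practice = 90, seed = 11)
  expect_identical(dim(unclass(cw)), c(260L, 90L))
  expect_equal(rowSums(unclass(cw)), rep(1, 260),
    tolerance = 1e-9, ignore_attr = TRUE
  )
  one <- simulate_crosswalk(n_area = 5, n_practice = 1, seed = 2)
  expect_equal(as.vector(unclass(one)), rep(1, 5))
})
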