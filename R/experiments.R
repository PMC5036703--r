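#' MCMC versus numerical-integration oracle on a toy outcome model
#'
#' Builds a 3-practice toy in which the latent quality scores, the
#' measurement parameters and all outcome parameters except the quality
#' coefficient are held fixed, so the posterior of that single coefficient
#' is available by fine-grid numerical integration. The same posterior is
#' then sampled by the package's MCMC, giving an end-to-end correctness
#' check of the sampler against an independent deterministic route.
#'
#' @param seed Integer seed (data generation and sampling).
#' @param iterations,burn_in MCMC effort.
#' @return A list with `grid_mean`, `grid_sd`, `mcmc_mean`, `mcmc_sd` and
#'   the toy data.
#' @export
grid_oracle_experiment <- function(seed = 1L, iterations = 20000,
                                   burn_in = 4000) {
  set.seed(seed)
  f <- c(-1, 0, 1)
  e_cnt <- c(20, 20, 20)
  g0 <- 0.02
  g1_true <- -0.25
  y <- stats::rpois(3, e_cnt * exp(g0 + g1_true * f))
  n <- c(200L, 200L, 200L)
  z <- stats::rbinom(3, n, stats::plogis(1.5 + f))
  tab <- practice_table(tibble::tibble(
    practice_id = c("T1", "T2", "T3"),
    z_1 = z, n_1 = n,
    admissions = y,
    deprivation = 0, morbidity = 0, gp_rate = 0, list_size = 0
  ), n_quality = 1, n_access = 0)
  tab$expected <- e_cnt

  prior_sd <- 10
  # fine-grid numerical posterior for the quality coefficient
  grid <- seq(-3, 3, by = 0.001)
  logpost <- vapply(grid, function(g1) {
    sum(y * (g0 + g1 * f) - e_cnt * exp(g0 + g1 * f))
  }, numeric(1)) + stats::dnorm(grid, 0, prior_sd, log = TRUE)
  wgt <- exp(logpost - max(logpost))
  wgt <- wgt / sum(wgt)
  grid_mean <- sum(wgt * grid)
  grid_sd <- sqrt(sum(wgt * (grid - grid_mean)^2))

  cfg <- model_config(1, n_quality = 1, n_access = 0, coef_prior_sd = prior_sd)
  fit <- fit_admissions_sem(
    tab, cfg,
    chains = 1, iterations = iterations, burn_in = burn_in, thin = 2,
    seed = seed,
    fixed = list(
      f = f, u = rep(0, 3), alpha = 0,
      eps = matrix(0, 3, 1), sigma = 0, delta = 1.5, lambda = 1,
      psi = c(0.5, 0.5),
      gamma = c(intercept = g0)
    )
  )
  draws <- stacked_pars(fit)[, "gamma_quality"]
  list(
    grid_mean = grid_mean, grid_sd = grid_sd,
    mcmc_mean = mean(draws), mcmc_sd = stats::sd(draws),
    table = tab
  )
}

#' Parameter-recovery experiment at study scale
#'
#' Repeatedly simulates 90-practice datasets at the calibrated generative
#' truths, refits the full structural model, and records whether each 95%
#' credible interval covers its true value, the sign of the posterior mean
#' latent correlation, and (optionally) the posterior predictive check
#' p-values for every observed variable.
#'
#' @param n_rep Number of replicate datasets.
#' @param seed Integer root seed.
#' @param n_practice Practices per replicate.
#' @param iterations,burn_in,thin MCMC effort per replicate (single chain).
#' @param ppc Also run the predictive checks on each fit.
#' @return A list with `coverage` (one row per replicate and parameter:
#'   `rep`, `term`, `truth`, `estimate`, `covered`), `rho_mean` (per
#'   replicate), and `ppc` (one row per replicate and variable) when
#'   requested.
#' @export
recovery_experiment <- function(n_rep = 50, seed = 1L, n_practice = 90,
                                iterations = 3500, burn_in = 1500, thin = 4,
                                ppc = FALSE) {
  truth <- default_parameters(3)
  check <- c(
    gamma_quality = truth$gamma[["quality"]],
    gamma_deprivation = truth$gamma[["deprivation"]],
    gamma_poor_access = truth$gamma[["poor_access"]],
    gamma_morbidity = truth$gamma[["morbidity"]],
    beta_depr_access = truth$beta[["depr_access"]],
    beta_listsize_access = truth$beta[["listsize_access"]],
    rho = truth$rho
  )
  one <- function(r) {
    tab <- simulate_practice_data(
      generator_config(n_practice = n_practice, seed = seed + 1000L + r)
    )
    fit <- fit_admissions_sem(
      tab, model_config(3),
      chains = 1, iterations = iterations, burn_in = burn_in, thin = thin,
      seed = seed + 2000L + r
    )
    td <- tidy(fit)
    td <- td[match(names(check), td$term), ]
    cov <- tibble::tibble(
      rep = r, term = names(check), truth = unname(check),
      estimate = td$estimate,
      covered = td$conf.low <= check & check <= td$conf.high
    )
    pp <- NULL
    if (ppc) {
      set.seed(seed + 3000L + r)
      vars <- c("admissions", paste0("z_", 1:4), paste0("w_", 1:4))
      pp <- tibble::tibble(
        rep = r, variable = vars,
        p_value = vapply(
          vars, function(v) posterior_predictive_check(fit, v), numeric(1)
        )
      )
    }
    list(
      coverage = cov,
      rho_mean = td$estimate[td$term == "rho"],
      ppc = pp
    )
  }
  runs <- lapply(seq_len(n_rep), one)
  list(
    coverage = dplyr::bind_rows(lapply(runs, `[[`, "coverage")),
    rho_mean = vapply(runs, `[[`, numeric(1), "rho_mean"),
    ppc = if (ppc) dplyr::bind_rows(lapply(runs, `[[`, "ppc")) else NULL
  )
}

#' WAIC model-comparison experiment
#'
#' Simulates data with genuine deprivation and morbidity effects on
#' admissions (the model-2 generative truths) and compares the
#' outcome-component WAIC of the quality-only model (model 1) against the
#' covariate-adjusted model (model 2) across replicates; the richer model
#' should fit better in most of them.
#'
#' @param n_rep Number of replicates.
#' @param seed Integer root seed.
#' @param n_practice Practices per replicate.
#' @param iterations,burn_in,thin MCMC effort per fit (single chain).
#' @return Tibble with `rep`, `waic_model1`, `waic_model2`.
#' @export
waic_comparison_experiment <- function(n_rep = 20, seed = 1L, n_practice = 90,
                                       iterations = 2200, burn_in = 900,
                                       thin = 3) {
  one <- function(r) {
    tab <- simulate_practice_data(
      generator_config(model = 2, n_practice = n_practice, seed = seed + 500L + r)
    )
    w <- vapply(1:2, function(m) {
      fit <- fit_admissions_sem(
        tab, model_config(m, n_quality = 4, n_access = 0),
        chains = 1, iterations = iterations, burn_in = burn_in, thin = thin,
        seed = seed + 600L + 10L * r + m
      )
      waic(fit, "outcome")$waic
    }, numeric(1))
    tibble::tibble(rep = r, waic_model1 = w[1], waic_model2 = w[2])
  }
  dplyr::bind_rows(lapply(seq_len(n_rep), one))
}

#' Simulation-based calibration on a reduced toy model
#'
#' Standard simulation-based calibration: parameters are drawn from their
#' priors, data are simulated from the model, the posterior is sampled, and
#' the rank of each true parameter among its thinned posterior draws is
#' recorded. If the sampler targets the correct posterior, the ranks are
#' uniform. The toy uses 3 practices and 2 quality indicators, with unit
#' Normal priors on the sampled parameters (outcome intercept, quality
#' effect and the free loading), the latent sd fixed at 1, and the
#' overdispersion terms switched off, keeping each replicate cheap while
#' exercising the latent-variable, measurement and outcome updates jointly.
#'
#' @param n_rep Number of replicates.
#' @param seed Integer root seed.
#' @param n_draws Posterior draws retained per replicate.
#' @param thin Thinning between retained draws (heavy, so ranks are
#'   computed from near-independent draws).
#' @return Matrix `n_rep` x 3 of integer ranks in `0..n_draws` with columns
#'   `gamma_intercept`, `gamma_quality`, `lambda[2]`.
#' @export
sbc_experiment <- function(n_rep = 200, seed = 1L, n_draws = 100, thin = 25) {
  I <- 3
  n_den <- rep(150L, I)
  e_cnt <- rep(25, I)
  burn <- 1000
  iterations <- burn + n_draws * thin
  params <- c("gamma_intercept", "gamma_quality", "lambda[2]")
  ranks <- matrix(NA_integer_, n_rep, length(params),
    dimnames = list(NULL, params)
  )
  for (r in seq_len(n_rep)) {
    set.seed(seed + 4000L + r)
    g0 <- stats::rnorm(1)
    g1 <- stats::rnorm(1)
    lam2 <- stats::rnorm(1)
    delta <- stats::rnorm(2)
    f <- stats::rnorm(I)
    z1 <- stats::rbinom(I, n_den, stats::plogis(delta[1] + f))
    z2 <- stats::rbinom(I, n_den, stats::plogis(delta[2] + lam2 * f))
    y <- stats::rpois(I, e_cnt * exp(g0 + g1 * f))
    tab <- practice_table(tibble::tibble(
      practice_id = paste0("S", seq_len(I)),
      z_1 = z1, n_1 = n_den, z_2 = z2, n_2 = n_den,
      admissions = y,
      deprivation = 0, morbidity = 0, gp_rate = 0, list_size = 0
    ), n_quality = 2, n_access = 0)
    tab$expected <- e_cnt
    cfg <- model_config(1,
      n_quality = 2, n_access = 0,
      coef_prior_sd = 1, latent_sd_fixed = c(1, 1)
    )
    fit <- fit_admissions_sem(
      tab, cfg,
      chains = 1, iterations = iterations, burn_in = burn, thin = thin,
      seed = seed + 5000L + r,
      fixed = list(
        alpha = 0, u = rep(0, I), sigma = c(0, 0), eps = matrix(0, I, 2)
      )
    )
    draws <- stacked_pars(fit)
    ranks[r, ] <- c(
      sum(draws[, "gamma_intercept"] < g0),
      sum(draws[, "gamma_quality"] < g1),
      sum(draws[, "lambda[2]"] < lam2)
    )
  }
  ranks
}

#' Chi-square uniformity test for calibration ranks
#'
#' @param ranks Integer ranks in `0..n_draws` (one column of
#'   [sbc_experiment()]).
#' @param n_draws Number of posterior draws the ranks were computed from.
#' @param bins Number of equal-width rank bins.
#' @return p-value of the chi-square test against uniformity.
#' @export
sbc_uniformity_pvalue <- function(ranks, n_draws = 100, bins = 10) {
  bin <- pmin(floor(ranks * bins / (n_draws + 1)), bins - 1)
  counts <- tabulate(bin + 1, nbins = bins)
  stats::chisq.test(counts)$p.value
}
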