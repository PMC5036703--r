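#' Generator configuration
#'
#' Describes the generative model used for synthetic practice tables:
#' study size, indicator counts and denominators, covariate distribution,
#' the generative parameter values, and the latent-factor family.
#'
#' Defaults mirror the motivating study: 90 practices, four clinical quality
#' indicators with register-sized denominators, four patient-survey access
#' indicators with survey-sized denominators, standardized covariates with a
#' 0.7 deprivation–morbidity correlation, and [default_parameters()] truths.
#'
#' @param n_practice Number of practices I.
#' @param n_quality,n_access Indicator counts J and K.
#' @param params Generative [sem_params()] truths.
#' @param model Model variant generating the outcome (see [model_config()]).
#' @param quality_denominators,access_denominators Length-2 integer ranges;
#'   denominators are drawn uniformly per practice and indicator.
#' @param cor_depr_morbidity Correlation between the (standardized)
#'   deprivation and morbidity covariates.
#' @param factor_family `"normal"` or `"student_t"`; the latter uses the
#'   Gamma(df/2, df/2) scale mixture with `df` from `params`.
#' @param mean_expected Mean expected admissions per practice, setting the
#'   exposure scale.
#' @param seed Integer seed used by [simulate_practice_data()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_practice = 90, n_quality = 4, n_access = 4,
                             params = default_parameters(model, n_quality, n_access),
                             model = 3,
                             quality_denominators = c(50L, 600L),
                             access_denominators = c(50L, 200L),
                             cor_depr_morbidity = 0.7,
                             factor_family = c("normal", "student_t"),
                             mean_expected = 50,
                             seed = 1L) {
  factor_family <- match.arg(factor_family)
  stopifnot(
    n_practice >= 2, quality_denominators[1] >= 1,
    access_denominators[1] >= 1, mean_expected > 0
  )
  if (factor_family == "student_t" && params$df <= 2) {
    stop("student_t factors require df > 2", call. = FALSE)
  }
  structure(
    list(
      n_practice = as.integer(n_practice),
      n_quality = as.integer(n_quality),
      n_access = as.integer(n_access),
      params = params, model = as.integer(model),
      quality_denominators = quality_denominators,
      access_denominators = access_denominators,
      cor_depr_morbidity = cor_depr_morbidity,
      factor_family = factor_family,
      mean_expected = mean_expected,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Simulate standardized covariates
#'
#' Deprivation and morbidity are drawn jointly normal with the configured
#' correlation; GP supply and list size are independent standard normals.
#' All covariates are on the standardized (mean 0, sd 1) scale on which the
#' model coefficients are interpreted.
#'
#' @param config A [generator_config()].
#' @return Tibble with `deprivation`, `morbidity`, `gp_rate`, `list_size`.
#' @export
simulate_covariates <- function(config) {
  I <- config$n_practice
  r <- config$cor_depr_morbidity
  d <- stats::rnorm(I)
  m <- r * d + sqrt(1 - r^2) * stats::rnorm(I)
  tibble::tibble(
    deprivation = d, morbidity = m,
    gp_rate = stats::rnorm(I), list_size = stats::rnorm(I)
  )
}

#' Simulate latent factor scores
#'
#' Draws (F, G) bivariate normal with covariate-driven means — deprivation
#' shifts quality, and deprivation, GP supply and list size shift poor
#' access — and covariance `Sigma / omega_i`, where `omega_i = 1` under the
#' normal family and `omega_i ~ Gamma(df/2, df/2)` under the Student-t scale
#' mixture.
#'
#' @param config A [generator_config()].
#' @param covariates Standardized covariate tibble (see
#'   [simulate_covariates()]).
#' @return Tibble with columns `f`, `g`, `omega`.
#' @export
simulate_latents <- function(config, covariates) {
  p <- config$params
  I <- config$n_practice
  if (abs(p$rho) >= 1 || any(p$psi <= 0)) {
    stop("latent covariance is not positive definite", call. = FALSE)
  }
  omega <- if (config$factor_family == "student_t") {
    stats::rgamma(I, p$df / 2, p$df / 2)
  } else {
    rep(1, I)
  }
  m_f <- p$beta[["depr_quality"]] * covariates$deprivation
  m_g <- p$beta[["depr_access"]] * covariates$deprivation +
    p$beta[["supply_access"]] * covariates$gp_rate +
    p$beta[["listsize_access"]] * covariates$list_size
  sd_f <- p$psi[1] / sqrt(omega)
  sd_g <- p$psi[2] / sqrt(omega)
  f <- m_f + sd_f * stats::rnorm(I)
  # conditional G | F for the bivariate draw
  g <- m_g + p$rho * sd_g / sd_f * (f - m_f) +
    sd_g * sqrt(1 - p$rho^2) * stats::rnorm(I)
  tibble::tibble(f = f, g = g, omega = omega)
}

#' Simulate binomial indicator counts
#'
#' Denominators are drawn uniformly over the configured ranges; attainment
#' (and poor-rating) probabilities follow the logistic-normal measurement
#' model `logit(pi_ij) = delta_j + lambda_j F_i + eps_ij` with
#' `eps_ij ~ Normal(0, sigma_j^2)`, and counts are binomial.
#'
#' @param config A [generator_config()].
#' @param latents Tibble from [simulate_latents()].
#' @return List with matrices `Z`, `N`, `W`, `V`, `eps`, `e`.
#' @export
simulate_indicators <- function(config, latents) {
  p <- config$params
  I <- config$n_practice
  J <- config$n_quality
  K <- config$n_access
  draw_block <- function(m, rng, delta, lambda, sds, scores) {
    if (m == 0) {
      empty <- matrix(0, I, 0)
      return(list(num = empty, den = empty, noise = empty))
    }
    den <- matrix(
      sample(seq(rng[1], rng[2]), I * m, replace = TRUE), I, m
    )
    noise <- matrix(stats::rnorm(I * m), I, m) *
      matrix(sds, I, m, byrow = TRUE)
    theta <- outer(scores, lambda) + matrix(delta, I, m, byrow = TRUE) + noise
    num <- matrix(stats::rbinom(I * m, as.vector(den), stats::plogis(as.vector(theta))), I, m)
    list(num = num, den = den, noise = noise)
  }
  q <- draw_block(
    J, config$quality_denominators, p$delta, p$lambda, p$sigma, latents$f
  )
  a <- if (config$model >= 3 && K > 0) {
    draw_block(
      K, config$access_denominators, p$eta, p$kappa, p$tau, latents$g
    )
  } else {
    draw_block(0, config$access_denominators, numeric(0), numeric(0), numeric(0), latents$g)
  }
  list(Z = q$num, N = q$den, eps = q$noise, W = a$num, V = a$den, e = a$noise)
}

#' Simulate admission counts
#'
#' Given latent scores, covariates and exposure, draws
#' `Y_i ~ Poisson(E_i * nu_i)` with
#' `log(nu_i)` following the configured model variant plus a
#' `Normal(0, alpha^2)` log-scale random effect.
#'
#' @param config A [generator_config()].
#' @param latents Tibble from [simulate_latents()].
#' @param covariates Covariate tibble.
#' @param expected Positive exposure vector.
#' @return List with integer `y` and the random effects `u`.
#' @export
simulate_outcome <- function(config, latents, covariates, expected) {
  stopifnot(all(expected > 0))
  p <- config$params
  u <- stats::rnorm(config$n_practice, 0, p$alpha)
  nu <- linear_predictor_nu(
    p, list(f = latents$f, g = latents$g, u = u), covariates, config$model
  )
  list(y = stats::rpois(config$n_practice, expected * nu), u = u)
}

#' Simulate a complete practice table
#'
#' Runs the full generative model (covariates, latent factors, indicator
#' counts, exposure, outcome) and assembles a validated [practice_table()]
#' with expected counts computed from the diabetes-register basis. The
#' generative truth (parameters, latent values, random effects) is attached
#' as the `truth` attribute, retrievable with [simulation_truth()].
#'
#' @param config A [generator_config()].
#' @param seed Seed; defaults to the config's.
#' @return A [practice_table()] with a `truth` attribute.
#' @examples
#' tab <- simulate_practice_data(generator_config(n_practice = 20, seed = 1))
#' simulation_truth(tab)$params$gamma
#' @export
simulate_practice_data <- function(config = generator_config(), seed = config$seed) {
  set.seed(seed)
  I <- config$n_practice
  covs <- simulate_covariates(config)
  lat <- simulate_latents(config, covs)
  ind <- simulate_indicators(config, lat)
  register <- if (config$n_quality > 0) rowMeans(ind$N) else rep(1, I)
  exposure <- register / mean(register) * config$mean_expected
  out <- simulate_outcome(config, lat, covs, exposure)
  df <- tibble::tibble(practice_id = sprintf("P%03d", seq_len(I)))
  add_block <- function(df, prefix) {
    mat <- ind[[prefix]]
    nm <- c(Z = "z", N = "n", W = "w", V = "v")[[prefix]]
    for (j in seq_len(ncol(mat))) df[[paste0(nm, "_", j)]] <- as.integer(mat[, j])
    df
  }
  for (b in c("Z", "N", "W", "V")) df <- add_block(df, b)
  df$admissions <- as.integer(out$y)
  df <- dplyr::bind_cols(df, covs)
  tab <- practice_table(df,
    n_quality = config$n_quality,
    n_access = if (config$model >= 3) config$n_access else 0L
  )
  tab <- compute_expected_counts(tab, basis = "diabetes_register")
  attr(tab, "truth") <- list(
    params = config$params,
    latents = tibble::tibble(
      f = lat$f, g = lat$g, omega = lat$omega, u = out$u
    ),
    eps = ind$eps, e = ind$e,
    exposure = exposure,
    config = config
  )
  tab
}

#' @rdname simulate_practice_data
#' @param table A table produced by [simulate_practice_data()].
#' @export
simulation_truth <- function(table) attr(table, "truth")

#' Simulate a population crosswalk
#'
#' Each area is served by a small random subset of practices (1 to
#' `max_practices`), with population shares drawn from a symmetric
#' Dirichlet; rows are exactly stochastic.
#'
#' @param n_area Number of areas L.
#' @param n_practice Number of practices I.
#' @param max_practices Largest number of practices serving one area.
#' @param seed Integer seed.
#' @return A [crosswalk_matrix()] of dimension L x I.
#' @export
simulate_crosswalk <- function(n_area = 260, n_practice = 90,
                               max_practices = 4, seed = 1L) {
  stopifnot(n_area >= 1, n_practice >= 1)
  set.seed(seed)
  m <- matrix(0, n_area, n_practice,
    dimnames = list(
      sprintf("A%04d", seq_len(n_area)),
      sprintf("P%03d", seq_len(n_practice))
    )
  )
  for (l in seq_len(n_area)) {
    k <- sample(seq_len(min(max_practices, n_practice)), 1)
    idx <- sample(n_practice, k)
    w <- stats::rgamma(k, 2, 1)
    m[l, idx] <- w / sum(w)
  }
  crosswalk_matrix(m)
}
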