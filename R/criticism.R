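#' Component-wise WAIC
#'
#' Widely applicable information criterion computed from the stored
#' pointwise log-likelihood cells of one likelihood component:
#' `WAIC = -2 (lppd - p_waic)` with
#' `lppd = sum_cells log mean_draws exp(ll)` (evaluated with log-sum-exp
#' stabilization) and `p_waic = sum_cells var_draws(ll)`. Cells are one per
#' practice for the admission outcome and one per (practice, indicator) for
#' the measurement components; lower WAIC indicates better fit.
#'
#' @param fit A `sem_fit` object.
#' @param component `"outcome"`, `"quality"` or `"access"`.
#' @return A one-row tibble with `component`, `lppd`, `p_waic`, `waic`.
#' @export
waic <- function(fit, component = c("outcome", "quality", "access")) {
  component <- match.arg(component)
  ll <- stacked_pointwise(fit, component)
  s <- nrow(ll)
  mx <- apply(ll, 2, max)
  lppd_cells <- mx + log(colMeans(exp(sweep(ll, 2, mx))))
  p_cells <- apply(ll, 2, stats::var)
  if (s == 1) p_cells <- rep(0, ncol(ll))
  lppd <- sum(lppd_cells)
  p_waic <- sum(p_cells)
  tibble::tibble(
    component = component, lppd = lppd, p_waic = p_waic,
    waic = -2 * (lppd - p_waic)
  )
}

# draws x practices matrix of relative risks nu implied by the retained
# draws (parameters, latent scores and outcome random effects)
posterior_nu_draws <- function(fit) {
  pars <- stacked_pars(fit)
  f <- stacked_latents(fit, "f")
  u <- stacked_latents(fit, "u")
  tab <- fit$table
  terms <- outcome_terms(fit$config$model)
  lp <- sweep(f, 1, pars[, "gamma_quality"], "*") + pars[, "gamma_intercept"] + u
  if ("deprivation" %in% terms) {
    lp <- lp + outer(pars[, "gamma_deprivation"], tab$deprivation)
  }
  if ("morbidity" %in% terms) {
    lp <- lp + outer(pars[, "gamma_morbidity"], tab$morbidity)
  }
  if ("poor_access" %in% terms) {
    g <- stacked_latents(fit, "g")
    lp <- lp + sweep(g, 1, pars[, "gamma_poor_access"], "*")
  }
  exp(lp)
}

# draws x practices success probabilities for one indicator column
posterior_prob_draws <- function(fit, block, j) {
  pars <- stacked_pars(fit)
  I <- nrow(fit$table)
  if (block == "quality") {
    scores <- stacked_latents(fit, "f")
    noise <- stacked_latents(fit, "eps")[, (j - 1) * I + seq_len(I), drop = FALSE]
    lam <- pars[, sprintf("lambda[%d]", j)]
    int <- pars[, sprintf("delta[%d]", j)]
  } else {
    scores <- stacked_latents(fit, "g")
    if (is.null(scores)) stop("model has no access component", call. = FALSE)
    noise <- stacked_latents(fit, "e")[, (j - 1) * I + seq_len(I), drop = FALSE]
    lam <- pars[, sprintf("kappa[%d]", j)]
    int <- pars[, sprintf("eta[%d]", j)]
  }
  stats::plogis(sweep(scores, 1, lam, "*") + int + noise)
}

#' Posterior predictive check
#'
#' For each retained draw, a replicate of the chosen variable is simulated
#' from its likelihood at that draw's parameters and latent values, and a
#' chi-square discrepancy `T(x; theta) = sum_i (x_i - E_i)^2 / Var_i` is
#' compared between replicate and observed data. The reported p-value is
#' the proportion of draws with `T(rep) >= T(obs)`; values near 0 or 1
#' signal misfit, while the central band indicates a satisfactory model.
#'
#' @param fit A `sem_fit` object.
#' @param variable `"admissions"`, a quality column name (`"z_1"`, ...), or
#'   an access column name (`"w_1"`, ...).
#' @param observed Optional replacement vector of observed counts (used in
#'   misfit tests); defaults to the fitted table's.
#' @return Scalar p-value in [0, 1].
#' @export
posterior_predictive_check <- function(fit, variable, observed = NULL) {
  tab <- fit$table
  I <- nrow(tab)
  if (variable == "admissions") {
    nu <- posterior_nu_draws(fit)
    mu <- sweep(nu, 2, tab$expected, "*")
    obs <- if (is.null(observed)) tab$admissions else observed
    s <- nrow(mu)
    rep_mat <- matrix(stats::rpois(s * I, mu), s, I)
    vv <- pmax(mu, 1e-12)
    t_obs <- rowSums((matrix(obs, s, I, byrow = TRUE) - mu)^2 / vv)
    t_rep <- rowSums((rep_mat - mu)^2 / vv)
  } else if (grepl("^z_[0-9]+$", variable) || grepl("^w_[0-9]+$", variable)) {
    j <- as.integer(sub("^[zw]_", "", variable))
    block <- if (startsWith(variable, "z")) "quality" else "access"
    den_col <- if (block == "quality") paste0("n_", j) else paste0("v_", j)
    if (!den_col %in% names(tab)) {
      stop("unknown variable: ", variable, call. = FALSE)
    }
    den <- tab[[den_col]]
    pi_mat <- posterior_prob_draws(fit, block, j)
    s <- nrow(pi_mat)
    mu <- sweep(pi_mat, 2, den, "*")
    vv <- pmax(mu * (1 - pi_mat), 1e-12)
    obs <- if (is.null(observed)) tab[[variable]] else observed
    rep_mat <- matrix(
      stats::rbinom(s * I, rep(den, each = s), pi_mat), s, I
    )
    t_obs <- rowSums((matrix(obs, s, I, byrow = TRUE) - mu)^2 / vv)
    t_rep <- rowSums((rep_mat - mu)^2 / vv)
  } else {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  mean(t_rep >= t_obs)
}

#' Posterior sign probability of a coefficient
#'
#' @param fit A `sem_fit` object.
#' @param coefficient A retained parameter name (e.g. `"gamma_quality"`).
#' @return A one-row tibble with `term`, `prob_negative`, `prob_positive`.
#' @export
sign_probability <- function(fit, coefficient) {
  draws <- stacked_pars(fit)
  if (!coefficient %in% colnames(draws)) {
    stop("coefficient '", coefficient, "' was not sampled", call. = FALSE)
  }
  x <- draws[, coefficient]
  tibble::tibble(
    term = coefficient,
    prob_negative = mean(x < 0),
    prob_positive = mean(x > 0)
  )
}

#' Marginal Bayes factor from a posterior sign probability
#'
#' Under a prior that is neutral with regard to the sign of a coefficient
#' (prior odds 1), the posterior probability `p` of a given sign converts
#' directly to a marginal Bayes factor `p / (1 - p)` for that sign
#' hypothesis. For example, a posterior probability of 0.918 that a
#' coefficient is negative corresponds to a Bayes factor of 11.2.
#'
#' @param p Posterior sign probability in (0, 1); vectorized.
#' @return Bayes factor(s); `p` of exactly 0 or 1 returns 0 or `Inf` with a
#'   warning, since a degenerate Monte-Carlo estimate cannot be converted
#'   meaningfully.
#' @examples
#' marginal_bayes_factor(0.918) # ~11.2: strong evidence for the sign
#' marginal_bayes_factor(0.5) # 1: indifference
#' @export
marginal_bayes_factor <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (any(p %in% c(0, 1))) {
    warning(
      "sign probability of exactly 0 or 1 is a Monte-Carlo limit; ",
      "the Bayes factor is reported as 0/Inf"
    )
  }
  p / (1 - p)
}

#' Factor score versus admission risk, with LOWESS smooth
#'
#' Pairs each practice's posterior mean factor score with its posterior
#' mean relative risk of unplanned admission and adds a locally weighted
#' linear smooth (tricube weights).
#'
#' @param fit A `sem_fit` object.
#' @param factor `"quality"` or `"poor_access"`.
#' @param span Smoother span (fraction of points used per local fit).
#' @return A tibble sorted by score with `practice_id`, `score`,
#'   `relative_risk`, `smooth`.
#' @export
factor_risk_curve <- function(fit, factor = c("quality", "poor_access"),
                              span = 2 / 3) {
  factor <- match.arg(factor)
  score_draws <- if (factor == "quality") {
    stacked_latents(fit, "f")
  } else {
    stacked_latents(fit, "g")
  }
  if (is.null(score_draws)) {
    stop("factor '", factor, "' is not part of the fitted model", call. = FALSE)
  }
  score <- colMeans(score_draws)
  nu <- colMeans(posterior_nu_draws(fit))
  ord <- order(score)
  sm <- stats::lowess(score[ord], nu[ord], f = span, iter = 0)
  tibble::tibble(
    practice_id = fit$table$practice_id[ord],
    score = score[ord],
    relative_risk = nu[ord],
    smooth = sm$y
  )
}

#' Full model-criticism report
#'
#' Bundles component-wise WAIC, posterior predictive checks for every
#' observed variable (admissions plus each indicator column), and posterior
#' sign probabilities with marginal Bayes factors for the regression and
#' structural coefficients.
#'
#' @param fit A `sem_fit` object.
#' @param seed Seed for the predictive replicates.
#' @return A list of class `fit_report` with tibbles `waic`, `ppc`,
#'   `coefficients`.
#' @export
fit_report <- function(fit, seed = 1L) {
  set.seed(seed)
  has_access <- !is.null(fit$chains[[1]]$pointwise$access)
  comps <- c("outcome", "quality", if (has_access) "access")
  waic_tbl <- dplyr::bind_rows(lapply(comps, function(cp) waic(fit, cp)))
  J <- fit$config$n_quality
  K <- if (has_access) fit$config$n_access else 0L
  vars <- c("admissions", paste0("z_", seq_len(J)),
    if (K > 0) paste0("w_", seq_len(K)))
  ppc_tbl <- tibble::tibble(
    variable = vars,
    p_value = vapply(vars, function(v) posterior_predictive_check(fit, v), numeric(1))
  )
  draws <- stacked_pars(fit)
  coef_names <- grep("^(gamma_|beta_)", colnames(draws), value = TRUE)
  coef_tbl <- dplyr::bind_rows(lapply(coef_names, function(cn) sign_probability(fit, cn)))
  coef_tbl$bayes_factor_negative <- suppressWarnings(
    marginal_bayes_factor(coef_tbl$prob_negative)
  )
  coef_tbl$bayes_factor_positive <- suppressWarnings(
    marginal_bayes_factor(coef_tbl$prob_positive)
  )
  structure(
    list(waic = waic_tbl, ppc = ppc_tbl, coefficients = coef_tbl),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Model criticism report\n\nWAIC by component:\n")
  print(dplyr::mutate(x$waic, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 1))))
  cat("\nPosterior predictive checks:\n")
  print(dplyr::mutate(x$ppc, p_value = round(.data$p_value, 2)))
  cat("\nCoefficient sign probabilities:\n")
  print(dplyr::mutate(x$coefficients, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 3))))
  invisible(x)
}
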