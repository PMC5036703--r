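#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# split each chain's draws for one parameter in half; returns a matrix with
# one column per half-chain
split_chains <- function(x) {
  n <- floor(length(x) / 2)
  cbind(x[seq_len(n)], x[n + seq_len(n)])
}

# split-Rhat (Gelman-Rubin with halved chains); NA when the draws are
# constant
split_rhat <- function(chain_cols) {
  halves <- do.call(cbind, lapply(chain_cols, split_chains))
  n <- nrow(halves)
  w <- mean(apply(halves, 2, stats::var))
  b <- n * stats::var(colMeans(halves))
  if (!is.finite(w) || w == 0) {
    return(NA_real_)
  }
  sqrt(((n - 1) / n * w + b / n) / w)
}

# effective sample size via chain-averaged autocovariances with Geyer's
# initial positive sequence truncation
ess_draws <- function(chain_cols) {
  m <- length(chain_cols)
  n <- length(chain_cols[[1]])
  if (n < 4) {
    return(NA_real_)
  }
  acovs <- lapply(chain_cols, function(x) {
    stats::acf(x, lag.max = min(n - 1, 500), plot = FALSE, type = "covariance")$acf[, 1, 1]
  })
  acov <- Reduce(`+`, acovs) / m
  chain_vars <- vapply(chain_cols, stats::var, numeric(1))
  w <- mean(chain_vars)
  if (!is.finite(w) || w == 0) {
    return(NA_real_)
  }
  var_plus <- w * (n - 1) / n
  if (m > 1) {
    var_plus <- var_plus + stats::var(vapply(chain_cols, mean, numeric(1)))
  }
  rho <- 1 - (w - acov) / var_plus
  rho[1] <- 1
  # Geyer: sum over consecutive-lag pairs while the pair sums stay positive
  max_pair <- floor((length(rho) - 1) / 2)
  s <- 0
  for (t in seq_len(max_pair)) {
    pair <- rho[2 * t] + rho[2 * t + 1]
    if (pair < 0) break
    s <- s + pair
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}

#' Convergence diagnostics for a fitted model
#'
#' Split R-hat, effective sample size and Monte-Carlo standard error per
#' retained parameter. Parameters with split R-hat above `rhat_threshold`
#' are flagged. With a single chain, R-hat is still computed from the two
#' chain halves; constant parameters (e.g. an anchored loading) yield NA
#' R-hat and are flagged as degenerate rather than failing.
#'
#' @param fit A `sem_fit` object from [fit_admissions_sem()].
#' @param rhat_threshold Flagging threshold (default 1.05).
#' @return A tibble with `term`, `rhat`, `ess`, `mcse`, `flagged`.
#' @export
convergence_report <- function(fit, rhat_threshold = 1.05) {
  par_mats <- lapply(fit$chains, `[[`, "pars")
  terms <- colnames(par_mats[[1]])
  rows <- lapply(terms, function(tm) {
    cols <- lapply(par_mats, function(m) m[, tm])
    all_draws <- unlist(cols)
    rhat <- split_rhat(cols)
    ess <- ess_draws(cols)
    tibble::tibble(
      term = tm,
      rhat = rhat,
      ess = ess,
      mcse = if (is.na(ess) || ess == 0) NA_real_ else stats::sd(all_draws) / sqrt(ess),
      flagged = is.na(rhat) || rhat > rhat_threshold
    )
  })
  dplyr::bind_rows(rows)
}

#' Posterior summary table
#'
#' Mean, sd and central 95% interval per parameter (quantiles by linear
#' interpolation), together with the posterior probabilities that each
#' parameter is positive or negative — the summary layout used for
#' reporting regression coefficients and loadings.
#'
#' @param fit A `sem_fit` object.
#' @param probs Interval quantiles.
#' @return A tibble with one row per parameter.
#' @export
posterior_summaries <- function(fit, probs = c(0.025, 0.975)) {
  draws <- stacked_pars(fit)
  qs <- t(apply(draws, 2, stats::quantile, probs = probs, names = FALSE))
  tibble::tibble(
    term = colnames(draws),
    mean = unname(colMeans(draws)),
    sd = unname(apply(draws, 2, stats::sd)),
    conf.low = unname(qs[, 1]),
    conf.high = unname(qs[, 2]),
    prob_positive = unname(colMeans(draws > 0)),
    prob_negative = unname(colMeans(draws < 0))
  )
}

#' Tidy a fitted structural equation model
#'
#' @param x A `sem_fit` object.
#' @param conf.level Credible-interval level.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `prob_negative`, `prob_positive`.
#' @export
tidy.sem_fit <- function(x, conf.level = 0.95, ...) {
  a <- (1 - conf.level) / 2
  out <- posterior_summaries(x, probs = c(a, 1 - a))
  dplyr::rename(out, estimate = "mean", std.error = "sd")
}

#' One-row fit summary
#'
#' @param x A `sem_fit` object.
#' @param ... Unused.
#' @return A tibble with model id, dimensions, draw counts, component WAIC
#'   values and the largest split R-hat.
#' @export
glance.sem_fit <- function(x, ...) {
  conv <- convergence_report(x)
  w_out <- waic(x, "outcome")
  w_q <- waic(x, "quality")
  w_a <- if (!is.null(x$chains[[1]]$pointwise$access)) waic(x, "access") else NULL
  tibble::tibble(
    model = x$config$model,
    n_practice = nrow(x$table),
    chains = x$meta$chains,
    n_draws = x$meta$n_kept * x$meta$chains,
    waic_outcome = w_out$waic,
    waic_quality = w_q$waic,
    waic_access = if (is.null(w_a)) NA_real_ else w_a$waic,
    max_rhat = max(conv$rhat, na.rm = TRUE)
  )
}

#' Posterior mean latent scores
#'
#' @param fit A `sem_fit` object.
#' @return Tibble with `practice_id`, posterior mean and sd of the quality
#'   score and (when fitted) the poor-access score.
#' @export
latent_scores <- function(fit) {
  f <- stacked_latents(fit, "f")
  out <- tibble::tibble(
    practice_id = fit$table$practice_id,
    quality_mean = colMeans(f),
    quality_sd = apply(f, 2, stats::sd)
  )
  g <- stacked_latents(fit, "g")
  if (!is.null(g)) {
    out$poor_access_mean <- colMeans(g)
    out$poor_access_sd <- apply(g, 2, stats::sd)
  }
  out
}
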