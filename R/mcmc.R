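#' Initialize an MCMC chain
#'
#' Builds a starting state with a guaranteed finite log-posterior:
#' measurement intercepts at the pooled empirical logits (with a
#' (x + 0.5) / (n + 1) continuity correction so all-zero or saturated
#' columns stay finite), latent scores at zero plus a small seed-dependent
#' jitter, regression coefficients at zero plus jitter, overdispersion
#' scales at 0.1 and latent sds at 0.5.
#'
#' @param table A validated [practice_table()] with expected counts.
#' @param config A [model_config()].
#' @param seed Integer seed for the jitter.
#' @param fixed Named list of values to clamp (see
#'   [fit_admissions_sem()]).
#' @return A named list holding the full latent + parameter state.
#' @export
initialize_chain <- function(table, config, seed = 1L, fixed = list()) {
  set.seed(seed)
  mats <- indicator_matrices(table)
  I <- nrow(table)
  J <- config$n_quality
  K <- config$n_access
  jit <- function(n, s = 0.05) stats::rnorm(n, 0, s)
  pooled_logit <- function(num, den) {
    stats::qlogis((colSums(num) + 0.5) / (colSums(den) + 1))
  }
  state <- list(
    gamma = stats::setNames(
      jit(length(outcome_terms(config$model)), 0.01),
      outcome_terms(config$model)
    ),
    alpha = 0.1,
    lambda = c(1, jit(max(J - 1, 0), 0.1)),
    delta = pooled_logit(mats$Z, mats$N),
    sigma = rep(0.1, J),
    kappa = if (K > 0) c(1, jit(K - 1, 0.1)) else numeric(0),
    eta = if (K > 0) pooled_logit(mats$W, mats$V) else numeric(0),
    tau = rep(0.1, K),
    beta = c(
      depr_quality = 0, depr_access = 0,
      supply_access = 0, listsize_access = 0
    ),
    psi = if (is.null(config$latent_sd_fixed)) c(0.5, 0.5) else config$latent_sd_fixed,
    rho = 0,
    f = jit(I, 0.1),
    g = if (K > 0) jit(I, 0.1) else rep(0, I),
    u = rep(0, I),
    eps = matrix(0, I, J),
    e = matrix(0, I, K),
    omega = rep(1, I)
  )
  for (nm in names(fixed)) {
    if (nm == "gamma") {
      state$gamma[names(fixed$gamma)] <- fixed$gamma
    } else {
      state[[nm]] <- fixed[[nm]]
    }
  }
  state
}

#' Fit the structural equation model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs sampling of all parameters and latent
#' quantities. Latent scores, overdispersion effects and the outcome random
#' effects are updated with practice-wise random-walk proposals (their full
#' conditionals factor across practices); measurement parameters are updated
#' indicator-wise; scale parameters move on the log scale and the latent
#' correlation on the Fisher-z scale, with Jacobians included; the
#' Student-t mixture weights (model 4) have a conjugate Gamma update.
#' Proposal scales adapt towards a 20–50% acceptance rate during burn-in
#' and are frozen afterwards. Runs are deterministic given `seed`.
#'
#' @param table A validated [practice_table()] with `expected` filled in
#'   (covariates are used exactly as supplied; standardize first if that is
#'   the scale you want coefficients on).
#' @param config A [model_config()].
#' @param chains Number of chains (2 or more recommended).
#' @param iterations Total iterations per chain.
#' @param burn_in Iterations discarded (and used for adaptation).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param fixed Named list clamping components instead of sampling them:
#'   any of `f`, `g`, `u`, `eps`, `e`, `omega`, `alpha`, `lambda`, `delta`,
#'   `sigma`, `kappa`, `eta`, `tau`, `beta`, `psi`, `rho`, or `gamma` (a
#'   named subvector fixes just those outcome terms). Used for reduced and
#'   oracle-comparison runs.
#' @param progress Print a line every 1000 iterations.
#' @return An object of class `sem_fit`: retained draws (parameters and
#'   latents per chain), pointwise log-likelihood arrays per component, and
#'   run metadata.
#' @examples
#' \donttest{
#' tab <- simulate_practice_data(generator_config(n_practice = 30, seed = 1))
#' fit <- fit_admissions_sem(tab, model_config(3),
#'   chains = 2, iterations = 2000, burn_in = 1000, seed = 1
#' )
#' tidy(fit)
#' glance(fit)
#' }
#' @export
fit_admissions_sem <- function(table, config = model_config(),
                               chains = 2, iterations = 4000,
                               burn_in = floor(iterations / 2), thin = 5,
                               seed = 1L, fixed = list(), progress = FALSE) {
  validate_practice_table(table)
  if (!"expected" %in% names(table) || any(is.na(table$expected))) {
    stop("table needs expected counts; run compute_expected_counts() first",
      call. = FALSE
    )
  }
  if (iterations <= burn_in) stop("iterations must exceed burn_in", call. = FALSE)
  if (config$model >= 3 && attr(table, "n_access") < config$n_access) {
    stop("model ", config$model, " needs access indicators absent from the table",
      call. = FALSE
    )
  }
  chain_list <- lapply(seq_len(chains), function(ch) {
    run_chain(
      table, config, iterations, burn_in, thin,
      seed = seed + ch - 1L, fixed = fixed, progress = progress
    )
  })
  structure(
    list(
      chains = chain_list,
      config = config,
      table = table,
      meta = list(
        chains = chains, iterations = iterations, burn_in = burn_in,
        thin = thin, seed = seed,
        n_kept = nrow(chain_list[[1]]$pars),
        acceptance = chain_list[[1]]$acceptance
      )
    ),
    class = "sem_fit"
  )
}

# One chain of the adaptive Metropolis-within-Gibbs sampler. Works on
# unnormalized log-likelihoods; binomial/Poisson normalizing constants are
# added only when storing pointwise log-likelihood cells.
run_chain <- function(table, config, iterations, burn_in, thin, seed,
                      fixed = list(), progress = FALSE) {
  set.seed(seed)
  model <- config$model
  J <- config$n_quality
  K <- config$n_access
  has_access <- model >= 3 && K > 0
  mats <- indicator_matrices(table)
  Z <- mats$Z
  N <- mats$N
  W <- if (has_access) mats$W else matrix(0, nrow(table), 0)
  V <- if (has_access) mats$V else matrix(0, nrow(table), 0)
  I <- nrow(table)
  Y <- table$admissions
  logE <- log(table$expected)
  lw <- 1
  if (isTRUE(config$prior_only)) {
    # binomial likelihood with zero denominators is identically zero, and
    # the outcome term is weighted out, so the sampler targets the prior
    Z[] <- 0
    N[] <- 0
    if (has_access) {
      W[] <- 0
      V[] <- 0
    }
    lw <- 0
  }
  D <- table$deprivation
  Mo <- table$morbidity
  S1 <- table$gp_rate
  S2 <- table$list_size
  Cq <- lchoose(N, Z)
  Ca <- if (has_access) lchoose(V, W) else NULL
  Cy <- -lfactorial(Y)

  terms <- outcome_terms(model)
  free_beta <- switch(as.character(model),
    "1" = character(0), "2" = "depr_quality",
    c("depr_quality", "depr_access", "supply_access", "listsize_access")
  )
  cs <- config$coef_prior_sd
  ss <- config$scale_prior_sd

  st <- initialize_chain(table, config, seed = seed, fixed = fixed)
  is_fixed <- function(nm) nm %in% names(fixed)
  fixed_gamma <- if (is_fixed("gamma")) names(fixed$gamma) else character(0)
  psi_free <- is.null(config$latent_sd_fixed) && !is_fixed("psi")
  sample_eps <- !(is_fixed("eps") || (is_fixed("sigma") && all(st$sigma == 0)))
  sample_e <- has_access &&
    !(is_fixed("e") || (is_fixed("tau") && all(st$tau == 0)))
  sample_u <- !(is_fixed("u") || (is_fixed("alpha") && st$alpha == 0))
  sample_omega <- model == 4 && !is_fixed("omega")

  # ---- caches -------------------------------------------------------------
  row_mat <- function(v, m) matrix(v, I, m, byrow = TRUE)
  theta_q <- outer(st$f, st$lambda) + row_mat(st$delta, J) + st$eps
  llq <- Z * theta_q - N * softplus(theta_q)
  if (has_access) {
    theta_a <- outer(st$g, st$kappa) + row_mat(st$eta, K) + st$e
    lla <- W * theta_a - V * softplus(theta_a)
  }
  lin_pred <- function() {
    lp <- st$gamma[["intercept"]] + st$gamma[["quality"]] * st$f + st$u
    if ("deprivation" %in% terms) lp <- lp + st$gamma[["deprivation"]] * D
    if ("morbidity" %in% terms) lp <- lp + st$gamma[["morbidity"]] * Mo
    if ("poor_access" %in% terms) lp <- lp + st$gamma[["poor_access"]] * st$g
    lp
  }
  lp_out <- lin_pred()
  mu <- if (lw == 0) numeric(I) else exp(logE + lp_out)
  lly <- if (lw == 0) numeric(I) else Y * (logE + lp_out) - mu

  mean_f <- function() st$beta[["depr_quality"]] * D
  mean_g <- function() {
    st$beta[["depr_access"]] * D + st$beta[["supply_access"]] * S1 +
      st$beta[["listsize_access"]] * S2
  }
  if (!all(is.finite(llq)) || !all(is.finite(lly))) {
    stop("non-finite likelihood at initial values", call. = FALSE)
  }

  # ---- adaptive proposal scales -------------------------------------------
  sc <- list(
    f = rep(0.3, I), g = rep(0.3, I), u = rep(0.2, I),
    eps = rep(0.3, J), e = rep(0.3, K),
    delta = rep(0.1, J), lambda = rep(0.2, J), sigma = rep(0.4, J),
    eta = rep(0.1, K), kappa = rep(0.2, K), tau = rep(0.4, K),
    gamma = stats::setNames(rep(0.1, length(terms)), terms),
    shift_f = 0.1, shift_g = 0.1, shift_u = 0.1,
    scale_sigma = rep(0.3, J), scale_tau = rep(0.3, K), scale_alpha = 0.5,
    alpha = 0.5,
    beta = stats::setNames(rep(0.2, length(free_beta)), free_beta),
    psi = c(0.3, 0.3), rho = 0.4
  )
  acc <- lapply(sc, function(x) x * 0)
  batch <- 0L
  adapt <- function(iter) {
    batch <<- batch + 1L
    step <- min(0.5, 2 / sqrt(batch))
    for (nm in names(sc)) {
      rate <- acc[[nm]] / 50
      sc[[nm]] <<- sc[[nm]] * exp((rate - 0.3) * step)
      acc[[nm]] <<- acc[[nm]] * 0
    }
  }

  # ---- storage ------------------------------------------------------------
  keep_idx <- seq(burn_in + thin, iterations, by = thin)
  n_keep <- length(keep_idx)
  par_names <- c(
    paste0("gamma_", terms), "alpha",
    sprintf("lambda[%d]", seq_len(J)), sprintf("delta[%d]", seq_len(J)),
    sprintf("sigma[%d]", seq_len(J)),
    if (has_access) c(
      sprintf("kappa[%d]", seq_len(K)), sprintf("eta[%d]", seq_len(K)),
      sprintf("tau[%d]", seq_len(K))
    ),
    if (length(free_beta)) paste0("beta_", free_beta),
    "psi_quality",
    if (has_access) c("psi_access", "rho")
  )
  pars <- matrix(NA_real_, n_keep, length(par_names),
    dimnames = list(NULL, par_names)
  )
  draws_f <- matrix(NA_real_, n_keep, I)
  draws_g <- if (has_access) matrix(NA_real_, n_keep, I) else NULL
  draws_u <- matrix(NA_real_, n_keep, I)
  draws_eps <- matrix(NA_real_, n_keep, I * J)
  draws_e <- if (has_access) matrix(NA_real_, n_keep, I * K) else NULL
  draws_omega <- if (model == 4) matrix(NA_real_, n_keep, I) else NULL
  ll_out <- matrix(NA_real_, n_keep, I)
  ll_qual <- matrix(NA_real_, n_keep, I * J)
  ll_acc <- if (has_access) matrix(NA_real_, n_keep, I * K) else NULL
  kp <- 0L

  zero_I <- numeric(I)
  upd_outcome <- function(lp_new) {
    if (lw == 0) {
      return(list(lp = lp_new, mu = zero_I, lly = zero_I))
    }
    mu_new <- exp(logE + lp_new)
    list(lp = lp_new, mu = mu_new, lly = Y * (logE + lp_new) - mu_new)
  }

  for (iter in seq_len(iterations)) {
    c1 <- 1 / (1 - st$rho^2)
    p1 <- st$psi[1]
    p2 <- st$psi[2]

    # --- quality overdispersion effects eps_ij -----------------------------
    if (sample_eps) {
      prop <- st$eps + row_mat(sc$eps, J) * matrix(stats::rnorm(I * J), I, J)
      th_p <- theta_q + (prop - st$eps)
      ll_p <- Z * th_p - N * softplus(th_p)
      sig2 <- row_mat(pmax(st$sigma, 1e-12)^2, J)
      logr <- (ll_p - llq) - (prop^2 - st$eps^2) / (2 * sig2)
      take <- log(stats::runif(I * J)) < logr
      st$eps[take] <- prop[take]
      theta_q[take] <- th_p[take]
      llq[take] <- ll_p[take]
      acc$eps <- acc$eps + colMeans(matrix(take, I, J))
    }

    # --- latent quality scores F -------------------------------------------
    if (!is_fixed("f")) {
      mf <- mean_f()
      fp <- st$f + sc$f * stats::rnorm(I)
      th_p <- theta_q + outer(fp - st$f, st$lambda)
      ll_p <- Z * th_p - N * softplus(th_p)
      d_q <- rowSums(ll_p - llq)
      lp_p <- lp_out + st$gamma[["quality"]] * (fp - st$f)
      o <- upd_outcome(lp_p)
      fc <- st$f - mf
      fcp <- fp - mf
      if (has_access) {
        gc <- st$g - mean_g()
        d_pr <- -0.5 * st$omega * c1 *
          ((fcp^2 - fc^2) / p1^2 - 2 * st$rho * (fcp - fc) * gc / (p1 * p2))
      } else {
        d_pr <- -0.5 * st$omega * (fcp^2 - fc^2) / p1^2
      }
      logr <- d_q + (o$lly - lly) + d_pr
      take <- log(stats::runif(I)) < logr
      st$f[take] <- fp[take]
      theta_q[take, ] <- th_p[take, , drop = FALSE]
      llq[take, ] <- ll_p[take, , drop = FALSE]
      lp_out[take] <- o$lp[take]
      mu[take] <- o$mu[take]
      lly[take] <- o$lly[take]
      acc$f <- acc$f + take
    }

    if (has_access) {
      # --- access overdispersion effects e_ik ------------------------------
      if (sample_e) {
        prop <- st$e + row_mat(sc$e, K) * matrix(stats::rnorm(I * K), I, K)
        th_p <- theta_a + (prop - st$e)
        ll_p <- W * th_p - V * softplus(th_p)
        tau2 <- row_mat(pmax(st$tau, 1e-12)^2, K)
        logr <- (ll_p - lla) - (prop^2 - st$e^2) / (2 * tau2)
        take <- log(stats::runif(I * K)) < logr
        st$e[take] <- prop[take]
        theta_a[take] <- th_p[take]
        lla[take] <- ll_p[take]
        acc$e <- acc$e + colMeans(matrix(take, I, K))
      }

      # --- latent poor-access scores G --------------------------------------
      if (!is_fixed("g")) {
        mg <- mean_g()
        gp <- st$g + sc$g * stats::rnorm(I)
        th_p <- theta_a + outer(gp - st$g, st$kappa)
        ll_p <- W * th_p - V * softplus(th_p)
        d_a <- rowSums(ll_p - lla)
        lp_p <- lp_out + st$gamma[["poor_access"]] * (gp - st$g)
        o <- upd_outcome(lp_p)
        gc <- st$g - mg
        gcp <- gp - mg
        fc <- st$f - mean_f()
        d_pr <- -0.5 * st$omega * c1 *
          ((gcp^2 - gc^2) / p2^2 - 2 * st$rho * (gcp - gc) * fc / (p1 * p2))
        logr <- d_a + (o$lly - lly) + d_pr
        take <- log(stats::runif(I)) < logr
        st$g[take] <- gp[take]
        theta_a[take, ] <- th_p[take, , drop = FALSE]
        lla[take, ] <- ll_p[take, , drop = FALSE]
        lp_out[take] <- o$lp[take]
        mu[take] <- o$mu[take]
        lly[take] <- o$lly[take]
        acc$g <- acc$g + take
      }
    }

    # --- outcome random effects u ------------------------------------------
    if (sample_u) {
      up <- st$u + sc$u * stats::rnorm(I)
      o <- upd_outcome(lp_out + (up - st$u))
      a2 <- max(st$alpha, 1e-12)^2
      logr <- (o$lly - lly) - (up^2 - st$u^2) / (2 * a2)
      take <- log(stats::runif(I)) < logr
      st$u[take] <- up[take]
      lp_out[take] <- o$lp[take]
      mu[take] <- o$mu[take]
      lly[take] <- o$lly[take]
      acc$u <- acc$u + take
    }

    # --- Student-t scale-mixture weights (conjugate Gamma) ------------------
    if (sample_omega) {
      fc <- st$f - mean_f()
      gc <- st$g - mean_g()
      q0 <- c1 * (fc^2 / p1^2 - 2 * st$rho * fc * gc / (p1 * p2) + gc^2 / p2^2)
      st$omega <- stats::rgamma(I, config$df / 2 + 1, config$df / 2 + q0 / 2)
    }

    # --- measurement intercepts / loadings / overdispersion sds -------------
    meas_block <- function(which) {
      # which = "quality" or "access"
      if (which == "quality") {
        num <- Z; den <- N; th <- theta_q; ll <- llq
        scores <- st$f; m <- J
        int <- "delta"; load <- "lambda"; sdn <- "sigma"; noise <- st$eps
      } else {
        num <- W; den <- V; th <- theta_a; ll <- lla
        scores <- st$g; m <- K
        int <- "eta"; load <- "kappa"; sdn <- "tau"; noise <- st$e
      }
      if (!is_fixed(int)) {
        cur <- st[[int]]
        prop <- cur + sc[[int]] * stats::rnorm(m)
        th_p <- th + row_mat(prop - cur, m)
        ll_p <- num * th_p - den * softplus(th_p)
        logr <- colSums(ll_p - ll) +
          stats::dnorm(prop, 0, cs, log = TRUE) -
          stats::dnorm(cur, 0, cs, log = TRUE)
        take <- log(stats::runif(m)) < logr
        if (any(take)) {
          st[[int]][take] <<- prop[take]
          th[, take] <- th_p[, take, drop = FALSE]
          ll[, take] <- ll_p[, take, drop = FALSE]
        }
        acc[[int]] <<- acc[[int]] + take
      }
      if (!is_fixed(load) && m > 1) {
        cur <- st[[load]]
        prop <- cur + sc[[load]] * stats::rnorm(m)
        prop[1] <- 1 # anchor loading stays fixed
        th_p <- th + outer(scores, prop - cur)
        ll_p <- num * th_p - den * softplus(th_p)
        logr <- colSums(ll_p - ll) +
          stats::dnorm(prop, 0, cs, log = TRUE) -
          stats::dnorm(cur, 0, cs, log = TRUE)
        logr[1] <- -Inf
        take <- log(stats::runif(m)) < logr
        if (any(take)) {
          st[[load]][take] <<- prop[take]
          th[, take] <- th_p[, take, drop = FALSE]
          ll[, take] <- ll_p[, take, drop = FALSE]
        }
        acc[[load]] <<- acc[[load]] + take
      }
      if (!is_fixed(sdn)) {
        lp_one <- function(s, ssej, ni) {
          dhalfnorm_log(s, ss) - ni * log(s) - ssej / (2 * s^2)
        }
        if (config$shared_overdispersion) {
          # one shared sd for the block: single log-scale proposal
          cur1 <- st[[sdn]][1]
          prop1 <- cur1 * exp(sc[[sdn]][1] * stats::rnorm(1))
          sse <- sum(noise^2)
          logr <- lp_one(prop1, sse, I * m) - lp_one(cur1, sse, I * m) +
            log(prop1) - log(cur1)
          if (log(stats::runif(1)) < logr) {
            st[[sdn]][] <<- prop1
            acc[[sdn]] <<- acc[[sdn]] + 1
          }
        } else {
          cur <- st[[sdn]]
          prop <- cur * exp(sc[[sdn]] * stats::rnorm(m))
          ssev <- colSums(noise^2)
          logr <- lp_one(prop, ssev, I) - lp_one(cur, ssev, I) +
            log(prop) - log(cur)
          take <- log(stats::runif(m)) < logr
          st[[sdn]][take] <<- prop[take]
          acc[[sdn]] <<- acc[[sdn]] + take
        }
      }
      if (which == "quality") {
        theta_q <<- th
        llq <<- ll
      } else {
        theta_a <<- th
        lla <<- ll
      }
    }
    meas_block("quality")
    if (has_access) meas_block("access")

    # --- joint rescaling of random effects and their sd ---------------------
    # proposes (eps_.j, sigma_j) -> (c eps_.j, c sigma_j); the normal prior
    # on eps is invariant up to the Jacobian factor c, so the move walks
    # along the funnel axis that traps single-site updates when sigma is
    # small
    if (sample_eps && !is_fixed("sigma") && !config$shared_overdispersion) {
      cc <- exp(sc$scale_sigma * stats::rnorm(J))
      eps_p <- st$eps * row_mat(cc, J)
      th_p <- theta_q + (eps_p - st$eps)
      ll_p <- Z * th_p - N * softplus(th_p)
      logr <- colSums(ll_p - llq) +
        dhalfnorm_log(st$sigma * cc, ss) - dhalfnorm_log(st$sigma, ss) +
        log(cc)
      take <- log(stats::runif(J)) < logr
      if (any(take)) {
        st$sigma[take] <- st$sigma[take] * cc[take]
        st$eps[, take] <- eps_p[, take, drop = FALSE]
        theta_q[, take] <- th_p[, take, drop = FALSE]
        llq[, take] <- ll_p[, take, drop = FALSE]
      }
      acc$scale_sigma <- acc$scale_sigma + take
    }
    if (sample_e && !is_fixed("tau") && !config$shared_overdispersion) {
      cc <- exp(sc$scale_tau * stats::rnorm(K))
      e_p <- st$e * row_mat(cc, K)
      th_p <- theta_a + (e_p - st$e)
      ll_p <- W * th_p - V * softplus(th_p)
      logr <- colSums(ll_p - lla) +
        dhalfnorm_log(st$tau * cc, ss) - dhalfnorm_log(st$tau, ss) +
        log(cc)
      take <- log(stats::runif(K)) < logr
      if (any(take)) {
        st$tau[take] <- st$tau[take] * cc[take]
        st$e[, take] <- e_p[, take, drop = FALSE]
        theta_a[, take] <- th_p[, take, drop = FALSE]
        lla[, take] <- ll_p[, take, drop = FALSE]
      }
      acc$scale_tau <- acc$scale_tau + take
    }
    if (sample_u && !is_fixed("alpha")) {
      cc <- exp(sc$scale_alpha * stats::rnorm(1))
      up <- st$u * cc
      o <- upd_outcome(lp_out + (up - st$u))
      logr <- sum(o$lly - lly) +
        dhalfnorm_log(st$alpha * cc, ss) - dhalfnorm_log(st$alpha, ss) +
        log(cc)
      if (log(stats::runif(1)) < logr) {
        st$alpha <- st$alpha * cc
        st$u <- up
        lp_out <- o$lp
        mu <- o$mu
        lly <- o$lly
        acc$scale_alpha <- acc$scale_alpha + 1
      }
    }

    # --- recentring moves --------------------------------------------------
    # shift all latent scores by d and move the measurement intercepts the
    # opposite way (delta_j - lambda_j d), leaving the measurement
    # likelihood invariant; breaks the location trade-off between the
    # intercepts and the latent mean that slows single-site mixing
    if (!is_fixed("f") && !is_fixed("delta")) {
      d <- sc$shift_f * stats::rnorm(1)
      fc <- st$f - mean_f()
      if (has_access) {
        gc <- st$g - mean_g()
        d_pr <- -0.5 * sum(st$omega * c1 *
          (((fc + d)^2 - fc^2) / p1^2 - 2 * st$rho * d * gc / (p1 * p2)))
      } else {
        d_pr <- -0.5 * sum(st$omega * ((fc + d)^2 - fc^2)) / p1^2
      }
      delta_p <- st$delta - st$lambda * d
      o <- upd_outcome(lp_out + st$gamma[["quality"]] * d)
      logr <- d_pr + sum(o$lly - lly) +
        sum(stats::dnorm(delta_p, 0, cs, log = TRUE) -
          stats::dnorm(st$delta, 0, cs, log = TRUE))
      if (log(stats::runif(1)) < logr) {
        st$f <- st$f + d
        st$delta <- delta_p
        lp_out <- o$lp
        mu <- o$mu
        lly <- o$lly
        acc$shift_f <- acc$shift_f + 1
      }
    }
    if (has_access && !is_fixed("g") && !is_fixed("eta")) {
      d <- sc$shift_g * stats::rnorm(1)
      fc <- st$f - mean_f()
      gc <- st$g - mean_g()
      d_pr <- -0.5 * sum(st$omega * c1 *
        (((gc + d)^2 - gc^2) / p2^2 - 2 * st$rho * d * fc / (p1 * p2)))
      eta_p <- st$eta - st$kappa * d
      o <- upd_outcome(lp_out + st$gamma[["poor_access"]] * d)
      logr <- d_pr + sum(o$lly - lly) +
        sum(stats::dnorm(eta_p, 0, cs, log = TRUE) -
          stats::dnorm(st$eta, 0, cs, log = TRUE))
      if (log(stats::runif(1)) < logr) {
        st$g <- st$g + d
        st$eta <- eta_p
        lp_out <- o$lp
        mu <- o$mu
        lly <- o$lly
        acc$shift_g <- acc$shift_g + 1
      }
    }
    # shift the outcome random effects and compensate the intercept
    # (likelihood-invariant; mixes gamma_intercept against u)
    if (sample_u && !"intercept" %in% fixed_gamma) {
      d <- sc$shift_u * stats::rnorm(1)
      a2 <- max(st$alpha, 1e-12)^2
      g0p <- st$gamma[["intercept"]] + d
      logr <- -sum((st$u - d)^2 - st$u^2) / (2 * a2) +
        stats::dnorm(g0p, 0, cs, log = TRUE) -
        stats::dnorm(st$gamma[["intercept"]], 0, cs, log = TRUE)
      if (log(stats::runif(1)) < logr) {
        st$u <- st$u - d
        st$gamma[["intercept"]] <- g0p
        acc$shift_u <- acc$shift_u + 1
      }
    }

    # --- outcome regression coefficients ------------------------------------
    xmat <- list(
      intercept = 1, quality = st$f, deprivation = D,
      poor_access = if (has_access) st$g else NULL, morbidity = Mo
    )
    for (t in setdiff(terms, fixed_gamma)) {
      cur <- st$gamma[[t]]
      prop <- cur + sc$gamma[[t]] * stats::rnorm(1)
      o <- upd_outcome(lp_out + (prop - cur) * xmat[[t]])
      logr <- sum(o$lly - lly) +
        stats::dnorm(prop, 0, cs, log = TRUE) -
        stats::dnorm(cur, 0, cs, log = TRUE)
      if (log(stats::runif(1)) < logr) {
        st$gamma[[t]] <- prop
        lp_out <- o$lp
        mu <- o$mu
        lly <- o$lly
        acc$gamma[[t]] <- acc$gamma[[t]] + 1
      }
    }

    # --- outcome overdispersion sd alpha ------------------------------------
    if (!is_fixed("alpha") && sample_u) {
      cur <- st$alpha
      prop <- cur * exp(sc$alpha * stats::rnorm(1))
      ssu <- sum(st$u^2)
      lp_a <- function(a) dhalfnorm_log(a, ss) - I * log(a) - ssu / (2 * a^2)
      logr <- lp_a(prop) - lp_a(cur) + log(prop) - log(cur)
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        st$alpha <- prop
        acc$alpha <- acc$alpha + 1
      }
    }

    # --- structural coefficients beta ---------------------------------------
    if (length(free_beta) > 0 && !is_fixed("beta")) {
      bvn_quad <- function(mf, mg) {
        fc <- st$f - mf
        if (!has_access) {
          return(sum(st$omega * fc^2) / (2 * p1^2))
        }
        gc <- st$g - mg
        0.5 * sum(st$omega * c1 *
          (fc^2 / p1^2 - 2 * st$rho * fc * gc / (p1 * p2) + gc^2 / p2^2))
      }
      for (b in free_beta) {
        cur <- st$beta[[b]]
        prop <- cur + sc$beta[[b]] * stats::rnorm(1)
        q_cur <- bvn_quad(mean_f(), if (has_access) mean_g() else NULL)
        st$beta[[b]] <- prop
        q_prop <- bvn_quad(mean_f(), if (has_access) mean_g() else NULL)
        st$beta[[b]] <- cur
        logr <- (q_cur - q_prop) +
          stats::dnorm(prop, 0, cs, log = TRUE) -
          stats::dnorm(cur, 0, cs, log = TRUE)
        if (log(stats::runif(1)) < logr) {
          st$beta[[b]] <- prop
          acc$beta[[b]] <- acc$beta[[b]] + 1
        }
      }
    }

    # --- latent sds and correlation -----------------------------------------
    if (psi_free || (has_access && !is_fixed("rho"))) {
      fc <- st$f - mean_f()
      gc <- if (has_access) st$g - mean_g() else NULL
      bvn_lp <- function(s1, s2, r) {
        if (!has_access) {
          return(-I * log(s1) - sum(st$omega * fc^2) / (2 * s1^2))
        }
        cc <- 1 / (1 - r^2)
        -I * (log(s1) + log(s2) + 0.5 * log(1 - r^2)) -
          0.5 * sum(st$omega * cc *
            (fc^2 / s1^2 - 2 * r * fc * gc / (s1 * s2) + gc^2 / s2^2))
      }
      if (psi_free) {
        for (d in seq_len(if (has_access) 2 else 1)) {
          cur <- st$psi[d]
          prop <- cur * exp(sc$psi[d] * stats::rnorm(1))
          s1 <- if (d == 1) prop else st$psi[1]
          s2 <- if (d == 2) prop else st$psi[2]
          logr <- bvn_lp(s1, s2, st$rho) - bvn_lp(st$psi[1], st$psi[2], st$rho) +
            dhalfnorm_log(prop, ss) - dhalfnorm_log(cur, ss) +
            log(prop) - log(cur)
          if (log(stats::runif(1)) < logr) {
            st$psi[d] <- prop
            acc$psi[d] <- acc$psi[d] + 1
          }
        }
        p1 <- st$psi[1]
        p2 <- st$psi[2]
      }
      if (has_access && !is_fixed("rho")) {
        zc <- atanh(st$rho)
        zp <- zc + sc$rho * stats::rnorm(1)
        rp <- tanh(zp)
        logr <- bvn_lp(p1, p2, rp) - bvn_lp(p1, p2, st$rho) +
          log(1 - rp^2) - log(1 - st$rho^2)
        if (log(stats::runif(1)) < logr) {
          st$rho <- rp
          acc$rho <- acc$rho + 1
          c1 <- 1 / (1 - rp^2)
        }
      }
    }

    if (iter <= burn_in && iter %% 50 == 0) adapt(iter)
    if (progress && iter %% 1000 == 0) {
      message("iteration ", iter, "/", iterations)
    }

    if (iter > burn_in && (iter - burn_in) %% thin == 0) {
      kp <- kp + 1L
      pars[kp, ] <- c(
        st$gamma, st$alpha, st$lambda, st$delta, st$sigma,
        if (has_access) c(st$kappa, st$eta, st$tau),
        st$beta[free_beta], st$psi[1],
        if (has_access) c(st$psi[2], st$rho)
      )
      draws_f[kp, ] <- st$f
      draws_u[kp, ] <- st$u
      draws_eps[kp, ] <- st$eps
      if (has_access) {
        draws_g[kp, ] <- st$g
        draws_e[kp, ] <- st$e
      }
      if (model == 4) draws_omega[kp, ] <- st$omega
      ll_out[kp, ] <- lly + Cy
      ll_qual[kp, ] <- llq + Cq
      if (has_access) ll_acc[kp, ] <- lla + Ca
    }
  }

  list(
    pars = pars, f = draws_f, g = draws_g, u = draws_u,
    eps = draws_eps, e = draws_e, omega = draws_omega,
    pointwise = list(
      outcome = ll_out, quality = ll_qual,
      access = if (has_access) ll_acc else NULL
    ),
    acceptance = lapply(acc, function(a) a / (iterations - burn_in))
  )
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(
    "Bayesian structural equation model fit (model ", x$config$model, ")\n",
    "  practices: ", nrow(x$table),
    ", chains: ", x$meta$chains,
    ", kept draws/chain: ", x$meta$n_kept, "\n",
    sep = ""
  )
  invisible(x)
}

# retained parameter draws stacked across chains
stacked_pars <- function(fit) {
  do.call(rbind, lapply(fit$chains, `[[`, "pars"))
}

# retained latent draws stacked across chains ("f", "g", "u", "eps", "e")
stacked_latents <- function(fit, what) {
  parts <- lapply(fit$chains, `[[`, what)
  if (is.null(parts[[1]])) {
    return(NULL)
  }
  do.call(rbind, parts)
}

# pointwise log-likelihood cells (draws x cells) for one component
stacked_pointwise <- function(fit, component) {
  parts <- lapply(fit$chains, function(ch) ch$pointwise[[component]])
  if (is.null(parts[[1]])) {
    stop("component '", component, "' was not fitted", call. = FALSE)
  }
  do.call(rbind, parts)
}
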