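# small fixtures built in code, shared across test files

# hand-built 3-practice table with 2 quality and 2 access indicators
tiny_table <- function(n_access = 2) {
  df <- tibble::tibble(
    practice_id = c("A", "B", "C"),
    z_1 = c(80L, 45L, 90L), n_1 = c(100L, 60L, 95L),
    z_2 = c(70L, 40L, 88L), n_2 = c(100L, 60L, 95L),
    admissions = c(12L, 8L, 15L),
    deprivation = c(-1, 0, 1),
    morbidity = c(0.5, -0.5, 0),
    gp_rate = c(0.2, -0.2, 0),
    list_size = c(1, -1, 0)
  )
  if (n_access > 0) {
    for (k in seq_len(n_access)) {
      df[[paste0("w_", k)]] <- c(10L, 20L, 5L)
      df[[paste0("v_", k)]] <- c(100L, 110L, 90L)
    }
  }
  practice_table(df, n_quality = 2, n_access = n_access)
}

# a quick reduced-size fitted model on simulated data, cached per session
quick_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tab <- simulate_practice_data(generator_config(n_practice = 40, seed = 42))
      cache <<- fit_admissions_sem(
        tab, model_config(3),
        chains = 2, iterations = 1200, burn_in = 600, thin = 3, seed = 5
      )
    }
    cache
  }
})

# fabricate a minimal model-1 sem_fit from explicit draws, for tests that
# need exact control over the posterior (curves, WAIC arithmetic, ...)
fake_fit <- function(pars, f, u, table, pointwise = NULL, chains = 1) {
  n <- nrow(pars)
  per <- n %/% chains
  ch <- lapply(seq_len(chains), function(c) {
    idx <- (c - 1) * per + seq_len(per)
    list(
      pars = pars[idx, , drop = FALSE],
      f = f[idx, , drop = FALSE], g = NULL,
      u = u[idx, , drop = FALSE], eps = NULL, e = NULL, omega = NULL,
      pointwise = lapply(pointwise, function(m) m[idx, , drop = FALSE])
    )
  })
  structure(
    list(
      chains = ch, config = model_config(1, n_quality = 2, n_access = 0),
      table = table,
      meta = list(
        chains = chains, iterations = n, burn_in = 0, thin = 1,
        n_kept = per, seed = 1
      )
    ),
    class = "sem_fit"
  )
}
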