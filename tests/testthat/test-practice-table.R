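test_that("validation rejects malformed tables and names the offender", {
  tab <- tiny_table()
  expect_s3_class(tab, "practice_table")
  expect_identical(n_quality_indicators(tab), 2L)

  bad <- tibble::as_tibble(tab)
  bad$z_1[2] <- 70L # exceeds n_1 = 60
  expect_error(practice_table(bad, 2, 2), "B")

  bad2 <- tibble::as_tibble(tab)
  bad2$n_2[1] <- 0L
  expect_error(practice_table(bad2, 2, 2), "denominators below 1")

  expect_error(
    practice_table(dplyr::select(tibble::as_tibble(tab), -"morbidity"), 2, 2),
    "morbidity"
  )
  expect_error(
    {
      t2 <- tiny_table()
      t2$admissions[1] <- -1L
      validate_practice_table(t2)
    },
    "non-negative"
  )
})

test_that("CSV round trip preserves counts exactly and reals to machine precision", {
  tab <- simulate_practice_data(generator_config(n_practice = 15, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_practice_table(tab, path)
  back <- read_practice_table(path)
  for (cc in grep("^[znwv]_", names(tab), value = TRUE)) {
    expect_identical(as.integer(back[[cc]]), as.integer(tab[[cc]]))
  }
  for (cc in c("deprivation", "morbidity", "gp_rate", "list_size", "expected")) {
    expect_equal(back[[cc]], tab[[cc]], tolerance = 1e-12)
  }
})

test_that("schema mapping renames columns and missing columns error by name", {
  tab <- tiny_table(n_access = 2)
  df <- tibble::as_tibble(tab)
  names(df)[names(df) == "admissions"] <- "emergency_adm"
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, path)
  expect_error(read_practice_table(path), "admissions")
  got <- read_practice_table(path, schema = c(admissions = "emergency_adm"))
  expect_identical(got$admissions, tab$admissions)
  expect_error(
    read_practice_table(path, schema = c(admissions = "no_such_col")),
    "no_such_col"
  )
})

test_that("covariate standardization matches a two-pass oracle and is idempotent", {
  tab <- tiny_table()
  tab$deprivation <- c(1, 2, 3)
  std <- standardize_covariates(tab)
  expect_equal(std$deprivation, c(-1, 0, 1))

  # independent two-pass mean/variance oracle on a random column
  set.seed(9)
  tab$morbidity <- stats::rnorm(3, 5, 2)
  m <- sum(tab$morbidity) / 3
  v <- sum((tab$morbidity - m)^2) / 2
  std <- standardize_covariates(tab)
  expect_equal(std$morbidity, (tab$morbidity - m) / sqrt(v), tolerance = 1e-12)
  expect_equal(mean(std$morbidity), 0, tolerance = 1e-12)
  expect_equal(stats::sd(std$morbidity), 1, tolerance = 1e-12)

  # record allows exact back-transformation; re-standardizing changes nothing
  rec <- standardization_record(std)
  expect_equal(
    std$morbidity * rec$sd[rec$variable == "morbidity"] +
      rec$mean[rec$variable == "morbidity"],
    tab$morbidity
  )
  expect_equal(
    standardize_covariates(std)$morbidity, std$morbidity,
    tolerance = 1e-9
  )

  tab$gp_rate <- rep(2, 3)
  expect_error(standardize_covariates(tab), "gp_rate")
})

test_that("expected counts allocate the admission total proportionally", {
  tab <- tiny_table()
  tab$admissions <- c(0L, 4L, 0L)
  tab$list_size <- c(10, 30, 40)
  e <- compute_expected_counts(tab, basis = "list_size")
  expect_equal(e$expected, c(0.5, 1.5, 2), tolerance = 1e-12)

  # conservation for a random table, register basis
  tab2 <- simulate_practice_data(generator_config(n_practice = 30, seed = 8))
  tab2 <- compute_expected_counts(tab2)
  expect_equal(sum(tab2$expected), sum(tab2$admissions), tolerance = 1e-9)
  expect_true(all(tab2$expected > 0))

  tab$list_size <- c(1, 1, 0)
  expect_error(compute_expected_counts(tab, basis = "list_size"), "C")
})

test_that("generator round-trips a configured overall attainment rate", {
  # in the noise-free limit the pooled rate converges to the configured
  # intercept rate (92.1% for the blood-pressure indicator)
  p <- default_parameters(3)
  p$sigma[] <- 0
  p$tau[] <- 0
  p$psi <- c(1e-4, 1e-4)
  p$beta[] <- 0
  cfg <- generator_config(n_practice = 400, params = p, seed = 21)
  tab <- simulate_practice_data(cfg)
  rate <- sum(tab$z_1) / sum(tab$n_1)
  expect_equal(rate, 0.921, tolerance = 0.005)
})
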