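#' Human-readable labels for reported terms
#'
#' Maps internal parameter names to the row labels used in the package's
#' summary tables (e.g. `gamma_quality` to "Quality of Care").
#'
#' @param terms Character vector of internal term names.
#' @return Character vector of display labels (unknown terms pass through).
#' @export
term_labels <- function(terms) {
  lab <- c(
    gamma_intercept = "Intercept",
    gamma_quality = "Quality of Care",
    gamma_deprivation = "Deprivation",
    gamma_poor_access = "Poor Access",
    gamma_morbidity = "Diabetes morbidity",
    alpha = "Overdispersion parameter",
    beta_depr_quality = "Deprivation on quality of care",
    beta_depr_access = "Deprivation on poor access",
    beta_supply_access = "GP Supply (FTE GPs per 1000 Patients)",
    beta_listsize_access = "List Size (in 000s)",
    rho = "Correlation between constructs",
    psi_quality = "Quality score sd",
    psi_access = "Poor access score sd"
  )
  out <- unname(lab[terms])
  out[is.na(out)] <- terms[is.na(out)]
  out
}

pipeline_schema <- c("seed", "stages", "input", "simulate", "fit", "diagnose", "map")

validate_pipeline_config <- function(cfg) {
  bad <- setdiff(names(cfg), pipeline_schema)
  if (length(bad) > 0) {
    stop("config error: unknown key(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  stages <- cfg$stages %||% c("simulate", "fit", "diagnose", "map")
  bad_stage <- setdiff(stages, c("simulate", "fit", "diagnose", "map"))
  if (length(bad_stage) > 0) {
    stop("config error: unknown stage(s): ", paste(bad_stage, collapse = ", "),
      call. = FALSE
    )
  }
  cfg$stages <- stages
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the simulate / fit / diagnose / map pipeline
#'
#' Executes the requested stages in order against an output directory,
#' persisting every intermediate (canonical CSVs, a serialized fit, JSON
#' reports) so that any stage can be re-run in isolation, plus a manifest
#' recording the configuration hash, stage seeds, package version and
#' input-file digests. All randomness derives from the single root seed,
#' split deterministically per stage, so a rerun with the same config and
#' seed reproduces every summary file byte for byte.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Top-level keys: `seed`, `stages`, `input` (paths
#'   `practice_table` / `crosswalk` for pre-existing data), and per-stage
#'   blocks `simulate` (arguments of [generator_config()] plus `n_area`),
#'   `fit` (`model`, `chains`, `iterations`, `burn_in`, `thin`,
#'   `standardize` to standardize covariates and persist the record), `map`
#'   (`factor`).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with the objects produced by the executed
#'   stages (`table`, `crosswalk`, `fit`, `report`, `areas`) and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  stage_seed <- function(k) cfg$seed + k * 1000L

  res <- list()
  digests <- list()
  run_stage <- function(name, expr) {
    say("stage ", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  path <- function(f) file.path(out_dir, f)

  if ("simulate" %in% cfg$stages) {
    res$table <- run_stage("simulate", {
      sim <- cfg$simulate %||% list()
      gc_args <- sim[intersect(names(sim), names(formals(generator_config)))]
      gc_args$seed <- stage_seed(1L)
      gcfg <- do.call(generator_config, gc_args)
      tab <- simulate_practice_data(gcfg)
      write_practice_table(tab, path("practice_table.csv"))
      truth <- simulation_truth(tab)
      jsonlite::write_json(
        list(
          params = unclass(truth$params),
          model = gcfg$model, n_practice = gcfg$n_practice
        ),
        path("true_parameters.json"),
        auto_unbox = TRUE, digits = NA
      )
      res$crosswalk <- simulate_crosswalk(
        n_area = sim$n_area %||% 260, n_practice = gcfg$n_practice,
        seed = stage_seed(2L)
      )
      write_crosswalk(res$crosswalk, path("crosswalk.csv"))
      tab
    })
  }

  load_table <- function() {
    if (!is.null(res$table)) {
      return(res$table)
    }
    src <- cfg$input$practice_table %||% path("practice_table.csv")
    digests$practice_table <<- unname(tools::md5sum(src))
    read_practice_table(src)
  }
  load_crosswalk <- function() {
    if (!is.null(res$crosswalk)) {
      return(res$crosswalk)
    }
    src <- cfg$input$crosswalk %||% path("crosswalk.csv")
    digests$crosswalk <<- unname(tools::md5sum(src))
    read_crosswalk(src)
  }

  if ("fit" %in% cfg$stages) {
    res$fit <- run_stage("fit", {
      fc <- cfg$fit %||% list()
      tab <- load_table()
      if (!"expected" %in% names(tab) || any(is.na(tab$expected))) {
        tab <- compute_expected_counts(tab)
      }
      if (isTRUE(fc$standardize)) {
        tab <- standardize_covariates(tab)
        write_standardization_record(tab, path("standardization.json"))
      }
      mcfg <- model_config(
        model = fc$model %||% 3,
        n_quality = attr(tab, "n_quality"),
        n_access = attr(tab, "n_access")
      )
      fit <- fit_admissions_sem(
        tab, mcfg,
        chains = fc$chains %||% 4,
        iterations = fc$iterations %||% 20000,
        burn_in = fc$burn_in %||% 10000,
        thin = fc$thin %||% 5,
        seed = stage_seed(3L),
        progress = !quiet
      )
      summ <- posterior_summaries(fit)
      summ <- dplyr::mutate(summ, label = term_labels(.data$term), .after = "term")
      readr::write_csv(summ, path("posterior_summary.csv"), progress = FALSE)
      readr::write_csv(convergence_report(fit), path("convergence.csv"), progress = FALSE)
      readr::write_csv(latent_scores(fit), path("latent_scores.csv"), progress = FALSE)
      draws <- tibble::as_tibble(as.data.frame(stacked_pars(fit)))
      draws$chain <- rep(seq_len(fit$meta$chains), each = fit$meta$n_kept)
      readr::write_csv(draws, path("parameter_draws.csv"), progress = FALSE)
      saveRDS(fit, path("fit.rds"))
      fit
    })
  }

  load_fit <- function() {
    if (!is.null(res$fit)) {
      return(res$fit)
    }
    if (!file.exists(path("fit.rds"))) {
      stop("no fitted model found; run the fit stage first", call. = FALSE)
    }
    readRDS(path("fit.rds"))
  }

  if ("diagnose" %in% cfg$stages) {
    res$report <- run_stage("diagnose", {
      fit <- load_fit()
      rep <- fit_report(fit, seed = stage_seed(4L))
      readr::write_csv(rep$waic, path("waic.csv"), progress = FALSE)
      readr::write_csv(rep$ppc, path("ppc.csv"), progress = FALSE)
      coefs <- dplyr::mutate(rep$coefficients,
        label = term_labels(.data$term), .after = "term"
      )
      readr::write_csv(coefs, path("coefficients.csv"), progress = FALSE)
      jsonlite::write_json(
        lapply(unclass(rep), function(x) x),
        path("fit_report.json"),
        dataframe = "rows", auto_unbox = TRUE, digits = NA
      )
      readr::write_csv(
        factor_risk_curve(fit, "quality"),
        path("factor_risk_quality.csv"),
        progress = FALSE
      )
      if (fit$config$model >= 3) {
        readr::write_csv(
          factor_risk_curve(fit, "poor_access"),
          path("factor_risk_access.csv"),
          progress = FALSE
        )
      }
      rep
    })
  }

  if ("map" %in% cfg$stages) {
    res$areas <- run_stage("map", {
      fit <- load_fit()
      cw <- load_crosswalk()
      fac <- (cfg$map %||% list())$factor %||%
        if (fit$config$model >= 3) "poor_access" else "quality"
      areas <- aggregate_to_areas(fit, cw, factor = fac)
      readr::write_csv(areas, path("area_scores.csv"), progress = FALSE)
      areas
    })
  }

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    package = "caresem",
    version = as.character(utils::packageVersion("caresem")),
    created = format(Sys.time(), tz = "UTC"),
    config_hash = unname(tools::md5sum(tmp)),
    config_file = cfg_path,
    seed = cfg$seed,
    stage_seeds = list(
      simulate = stage_seed(1L), crosswalk = stage_seed(2L),
      fit = stage_seed(3L), diagnose = stage_seed(4L)
    ),
    stages = cfg$stages,
    input_digests = digests
  )
  unlink(tmp)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE)
  res$manifest <- manifest
  invisible(res)
}
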