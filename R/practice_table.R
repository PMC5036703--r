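#' Practice-level data tables
#'
#' A practice table holds one row per general-practice: binomial
#' quality-of-care indicators (numerator/denominator pairs `z_j`/`n_j`),
#' binomial poor-access indicators (`w_k`/`v_k`), the unplanned admission
#' count `admissions`, an exposure `expected` defining relative risk, and the
#' covariates `deprivation` (income deprivation score), `morbidity`
#' (age-standardised diabetes rate), `gp_rate` (FTE GPs per 1000 patients)
#' and `list_size` (registered patients, in thousands).
#'
#' @param data A data frame with the canonical columns (see Details).
#' @param n_quality,n_access Number of quality (J) and access (K) indicators;
#'   inferred from the column names when `NULL`.
#'
#' @details Canonical column names are `practice_id`, `z_1..z_J`, `n_1..n_J`,
#'   `w_1..w_K`, `v_1..v_K`, `admissions`, `expected` (optional until
#'   [compute_expected_counts()] is called), `deprivation`, `morbidity`,
#'   `gp_rate`, `list_size`. Counts must satisfy `0 <= z <= n`, `n >= 1`
#'   (and the analogue for access), `admissions >= 0`.
#'
#' @return A tibble of class `practice_table`.
#' @export
practice_table <- function(data, n_quality = NULL, n_access = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(n_quality)) {
    n_quality <- sum(grepl("^z_[0-9]+$", names(data)))
  }
  if (is.null(n_access)) {
    n_access <- sum(grepl("^w_[0-9]+$", names(data)))
  }
  out <- structure(data,
    class = c("practice_table", class(tibble::tibble())),
    n_quality = as.integer(n_quality), n_access = as.integer(n_access)
  )
  validate_practice_table(out)
  for (cc in c(grep("^[znwv]_[0-9]+$", names(out), value = TRUE), "admissions")) {
    out[[cc]] <- as.integer(out[[cc]])
  }
  out
}

#' Validate a practice table
#'
#' Checks dimensions, count integrity (numerators within denominators,
#' denominators at least 1, non-negative admissions, positive expected
#' counts) and presence of the covariate columns. Failures name the
#' offending practices and columns.
#'
#' @param table A [practice_table()].
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_practice_table <- function(table) {
  J <- attr(table, "n_quality")
  K <- attr(table, "n_access")
  needed <- c(
    "practice_id",
    if (J > 0) c(paste0("z_", seq_len(J)), paste0("n_", seq_len(J))),
    if (K > 0) c(paste0("w_", seq_len(K)), paste0("v_", seq_len(K))),
    "admissions", "deprivation", "morbidity", "gp_rate", "list_size"
  )
  missing <- setdiff(needed, names(table))
  if (length(missing) > 0) {
    stop("practice table is missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(table) < 1) stop("practice table has no rows", call. = FALSE)

  check_counts <- function(num, den, what) {
    z <- as.matrix(table[paste0(num, "_", seq_len(if (num == "z") J else K))])
    n <- as.matrix(table[paste0(den, "_", seq_len(if (num == "z") J else K))])
    if (any(z != round(z)) || any(n != round(n))) {
      stop(what, " counts must be integers", call. = FALSE)
    }
    if (any(n < 1)) {
      bad <- table$practice_id[apply(n < 1, 1, any)]
      stop(what, " denominators below 1 for practice(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    if (any(z < 0) || any(z > n)) {
      bad <- table$practice_id[apply(z < 0 | z > n, 1, any)]
      stop(what, " numerators outside [0, denominator] for practice(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  if (J > 0) check_counts("z", "n", "quality")
  if (K > 0) check_counts("w", "v", "access")

  if (any(table$admissions < 0) || any(table$admissions != round(table$admissions))) {
    stop("admissions must be non-negative integers", call. = FALSE)
  }
  if ("expected" %in% names(table) && any(!is.na(table$expected)) &&
    any(table$expected <= 0, na.rm = TRUE)) {
    stop("expected counts must be strictly positive", call. = FALSE)
  }
  invisible(table)
}

#' @export
#' @rdname practice_table
n_quality_indicators <- function(data) attr(data, "n_quality")

#' @export
#' @rdname practice_table
n_access_indicators <- function(data) attr(data, "n_access")

#' Extract indicator count matrices
#'
#' Returns the quality numerator/denominator matrices `Z`, `N` (I x J) and
#' the access matrices `W`, `V` (I x K) from a practice table.
#'
#' @param table A [practice_table()].
#' @return A list with integer matrices `Z`, `N`, `W`, `V`.
#' @export
indicator_matrices <- function(table) {
  J <- attr(table, "n_quality")
  K <- attr(table, "n_access")
  get <- function(prefix, m) {
    if (m == 0) {
      return(matrix(0L, nrow(table), 0))
    }
    x <- as.matrix(table[paste0(prefix, "_", seq_len(m))])
    storage.mode(x) <- "double"
    dimnames(x) <- NULL
    x
  }
  list(
    Z = get("z", J), N = get("n", J),
    W = get("w", K), V = get("v", K)
  )
}

#' Read a practice table from CSV
#'
#' @param path Path to a comma-separated UTF-8 file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the file's column names (values), e.g.
#'   `c(admissions = "emergency_adm")`. Unmapped canonical names are looked
#'   up directly.
#' @return A validated [practice_table()].
#' @examples
#' path <- system.file("extdata", "synthetic_practice_table.csv",
#'   package = "caresem"
#' )
#' tab <- read_practice_table(path)
#' tab <- standardize_covariates(compute_expected_counts(tab))
#' @export
read_practice_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    missing <- setdiff(unname(schema), names(raw))
    if (length(missing) > 0) {
      stop("schema maps to column(s) absent from file: ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    for (canon in names(schema)) {
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  count_cols <- grep("^(z|n|w|v)_[0-9]+$", names(raw), value = TRUE)
  for (cc in count_cols) {
    x <- raw[[cc]]
    if (any(is.na(x)) || any(x != round(x))) {
      stop("column ", cc, " does not parse as non-negative integer counts",
        call. = FALSE
      )
    }
  }
  practice_table(raw)
}

#' Write a practice table to CSV
#'
#' @param table A [practice_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_practice_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' Standardize model covariates
#'
#' Centres and scales `deprivation`, `morbidity`, `gp_rate` and `list_size`
#' to mean 0, sd 1, storing the original means and sds in a standardization
#' record (retrievable with [standardization_record()]) for
#' back-transformation of coefficients.
#'
#' @param table A [practice_table()] with at least two rows.
#' @return The table with standardized covariates and a `standardization`
#'   attribute.
#' @export
standardize_covariates <- function(table) {
  validate_practice_table(table)
  if (nrow(table) < 2) stop("need at least 2 practices", call. = FALSE)
  vars <- c("deprivation", "morbidity", "gp_rate", "list_size")
  rec <- tibble::tibble(
    variable = vars,
    mean = vapply(vars, function(v) mean(table[[v]]), numeric(1)),
    sd = vapply(vars, function(v) stats::sd(table[[v]]), numeric(1))
  )
  if (any(rec$sd == 0)) {
    stop("zero-variance covariate(s): ",
      paste(rec$variable[rec$sd == 0], collapse = ", "),
      call. = FALSE
    )
  }
  for (i in seq_along(vars)) {
    table[[vars[i]]] <- (table[[vars[i]]] - rec$mean[i]) / rec$sd[i]
  }
  attr(table, "standardization") <- rec
  table
}

#' @rdname standardize_covariates
#' @export
standardization_record <- function(table) attr(table, "standardization")

#' @rdname standardize_covariates
#' @param path Output path for the JSON standardization record.
#' @export
write_standardization_record <- function(table, path) {
  rec <- standardization_record(table)
  if (is.null(rec)) {
    stop("table has no standardization record; run standardize_covariates()",
      call. = FALSE
    )
  }
  jsonlite::write_json(rec, path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct expected admission counts
#'
#' Sets the exposure `expected` proportional to a basis of practice size so
#' that the relative risk of unplanned admission equals 1 when a practice
#' admits at the study-wide rate. The expected counts are internally
#' standardized: `sum(expected) == sum(admissions)` exactly.
#'
#' @param table A [practice_table()].
#' @param basis `"diabetes_register"` (default; the mean quality-indicator
#'   denominator, a proxy for the registered diabetes population) or
#'   `"list_size"`.
#' @return The table with its `expected` column filled in.
#' @export
compute_expected_counts <- function(table,
                                    basis = c("diabetes_register", "list_size")) {
  basis <- match.arg(basis)
  validate_practice_table(table)
  b <- switch(basis,
    diabetes_register = {
      J <- attr(table, "n_quality")
      if (J == 0) stop("no quality denominators to build a register basis", call. = FALSE)
      rowMeans(as.matrix(table[paste0("n_", seq_len(J))]))
    },
    list_size = table$list_size
  )
  if (any(b <= 0)) {
    stop("basis has non-positive value(s) for practice(s): ",
      paste(table$practice_id[b <= 0], collapse = ", "),
      call. = FALSE
    )
  }
  table$expected <- b * sum(table$admissions) / sum(b)
  table
}
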