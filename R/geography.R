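#' Aggregate practice scores to small areas
#'
#' Converts per-practice scores into area-level weighted averages using a
#' population crosswalk (the share of each area's population registered at
#' each practice). Scores can be supplied either as a tibble of posterior
#' means or as a fitted model, in which case aggregation is applied per
#' posterior draw and then summarized, propagating posterior uncertainty to
#' the area level.
#'
#' @param x A `sem_fit` object, or a data frame with `practice_id` and a
#'   numeric `score` column.
#' @param crosswalk A [crosswalk_matrix()] whose column names are practice
#'   ids present in `x`.
#' @param factor For a fitted model: `"quality"` or `"poor_access"`.
#' @return Tibble with `area_id`, `score_mean`, `score_sd` (NA when
#'   aggregating plain posterior means) and `covered_fraction` (the raw
#'   crosswalk row sum before renormalization).
#' @export
aggregate_to_areas <- function(x, crosswalk,
                               factor = c("poor_access", "quality")) {
  if (!inherits(crosswalk, "crosswalk")) {
    stop("crosswalk must be a crosswalk_matrix()", call. = FALSE)
  }
  w <- unclass(crosswalk)
  if (inherits(x, "sem_fit")) {
    factor <- match.arg(factor)
    draws <- if (factor == "quality") {
      stacked_latents(x, "f")
    } else {
      stacked_latents(x, "g")
    }
    if (is.null(draws)) {
      stop("factor '", factor, "' is not part of the fitted model", call. = FALSE)
    }
    colnames(draws) <- x$table$practice_id
    missing <- setdiff(colnames(w), colnames(draws))
    if (length(missing) > 0) {
      stop("crosswalk practice(s) absent from scores: ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    area_draws <- draws[, colnames(w), drop = FALSE] %*% t(w)
    score_mean <- unname(colMeans(area_draws))
    score_sd <- unname(apply(area_draws, 2, stats::sd))
  } else {
    x <- tibble::as_tibble(x)
    if (!all(c("practice_id", "score") %in% names(x))) {
      stop("score table needs columns practice_id and score", call. = FALSE)
    }
    missing <- setdiff(colnames(w), x$practice_id)
    if (length(missing) > 0) {
      stop("crosswalk practice(s) absent from scores: ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    s <- x$score[match(colnames(w), x$practice_id)]
    score_mean <- as.vector(w %*% s)
    score_sd <- rep(NA_real_, nrow(w))
  }
  tibble::tibble(
    area_id = rownames(w),
    score_mean = score_mean,
    score_sd = score_sd,
    covered_fraction = pmin(unname(attr(crosswalk, "covered_fraction")), 1)
  )
}
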