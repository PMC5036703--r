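#' Population crosswalk between small areas and practices
#'
#' A crosswalk is a row-stochastic L x I matrix whose entry (l, i) is the
#' proportion of area l's population registered with practice i. Rows whose
#' raw weights sum to less than 1 (partial coverage) are renormalized; the
#' original row sum is kept as the `covered_fraction` attribute.
#'
#' @param weights Non-negative numeric matrix, areas in rows, practices in
#'   columns; `dimnames` supply area and practice identifiers.
#' @return A matrix of class `crosswalk` with rows summing to 1.
#' @export
crosswalk_matrix <- function(weights) {
  weights <- as.matrix(weights)
  if (any(weights < 0)) stop("crosswalk weights must be non-negative", call. = FALSE)
  rs <- rowSums(weights)
  if (any(rs == 0)) {
    stop("crosswalk row(s) with zero total weight: ",
      paste(rownames(weights)[rs == 0], collapse = ", "),
      call. = FALSE
    )
  }
  out <- weights / rs
  structure(out, class = c("crosswalk", "matrix", "array"), covered_fraction = rs)
}

#' Read a crosswalk from a long-format CSV
#'
#' Expects columns `area_id`, `practice_id`, `weight`; one row per
#' (area, practice) pair with positive population share.
#'
#' @param path CSV path.
#' @return A [crosswalk_matrix()].
#' @export
read_crosswalk <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("area_id", "practice_id", "weight")
  missing <- setdiff(needed, names(long))
  if (length(missing) > 0) {
    stop("crosswalk file missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  areas <- unique(long$area_id)
  practices <- unique(long$practice_id)
  m <- matrix(0, length(areas), length(practices),
    dimnames = list(areas, practices)
  )
  m[cbind(
    match(long$area_id, areas),
    match(long$practice_id, practices)
  )] <- long$weight
  crosswalk_matrix(m)
}

#' Write a crosswalk as a long-format CSV
#'
#' Emits unnormalized weights (row-normalized weight times the covered
#' fraction) so that a read/write round trip is exact.
#'
#' @param crosswalk A [crosswalk_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crosswalk <- function(crosswalk, path) {
  cf <- attr(crosswalk, "covered_fraction")
  raw <- unclass(crosswalk) * cf
  long <- tibble::tibble(
    area_id = rep(rownames(raw), times = ncol(raw)),
    practice_id = rep(colnames(raw), each = nrow(raw)),
    weight = as.vector(raw)
  )
  long <- dplyr::filter(long, .data$weight > 0)
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}
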