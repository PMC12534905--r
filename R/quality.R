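#' Bin quality score
#'
#' The standard MAG ranking statistic: completeness minus five times
#' contamination, in percentage points. May be negative for badly
#' contaminated bins.
#'
#' @param completeness Percent in `[0, 100]`.
#' @param contamination Percent, `>= 0`.
#' @return `completeness - 5 * contamination` (vectorized).
#' @export
quality_score <- function(completeness, contamination) {
  if (any(is.na(completeness)) || any(completeness < 0 | completeness > 100))
    stop("completeness must be in [0, 100]", call. = FALSE)
  if (any(is.na(contamination)) || any(contamination < 0))
    stop("contamination must be >= 0", call. = FALSE)
  completeness - 5 * contamination
}

#' High-quality gate for representative selection
#'
#' A bin may serve as a cluster representative only if its completeness
#' exceeds 90 and its contamination is below 5 (both strict).
#'
#' @param quality A quality record (row of a quality table).
#' @return Logical.
#' @export
is_high_quality <- function(quality) {
  quality$completeness > 90 & quality$contamination < 5
}

#' Filter bins by purity
#'
#' A bin is retained iff its purity strictly exceeds `purity_threshold`,
#' i.e. contamination < 100 - threshold. Purity is defined as
#' 100 - min(contamination, 100).
#'
#' @param bins Named list of `sequence_bin`.
#' @param qualities Quality table covering every bin.
#' @param purity_threshold Percent in `[0, 100]`; default 95 (the `-p`
#'   flag of the command line).
#' @return List with `retained` (named list of bins) and `rejected`
#'   (data frame of bin_id, purity, reason).
#' @export
filter_by_purity <- function(bins, qualities, purity_threshold = 95) {
  stopifnot(purity_threshold >= 0, purity_threshold <= 100)
  keep <- vapply(bins, function(b) {
    q <- quality_for(qualities, b$bin_id)
    q$purity > purity_threshold
  }, logical(1))
  rejected <- if (any(!keep)) {
    ids <- names(bins)[!keep]
    data.frame(
      bin_id = ids,
      purity = vapply(ids, function(id) quality_for(qualities, id)$purity,
                      numeric(1)),
      reason = sprintf("purity <= %g", purity_threshold),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    data.frame(bin_id = character(0), purity = numeric(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  list(retained = bins[keep], rejected = rejected)
}

#' Filter bins by total length
#'
#' Retains bins whose total contig length is at least `min_length`
#' (inclusive boundary).
#'
#' @param bins Named list of `sequence_bin`.
#' @param min_length Minimum total length in bp; default 200 kb, the
#'   conventional floor below which a bin carries too little sequence to
#'   be a useful genome draft.
#' @return Named list of retained bins.
#' @export
filter_by_length <- function(bins, min_length = 200000) {
  stopifnot(min_length >= 0)
  keep <- vapply(bins, function(b) bin_length(b) >= min_length, logical(1))
  bins[keep]
}

#' Filter quality records by completeness
#'
#' Applied to the final output set (the `-c` flag): records are retained
#' iff completeness >= `min_completeness` (inclusive). Low-completeness
#' bins are deliberately NOT filtered before clustering — their sequence
#' can still improve a merged bin.
#'
#' @param qualities Quality table (or any data frame with a
#'   `completeness` column).
#' @param min_completeness Percent in `[0, 100]`; default 50.
#' @return The retained rows.
#' @export
filter_by_completeness <- function(qualities, min_completeness = 50) {
  stopifnot(min_completeness >= 0, min_completeness <= 100)
  qualities[qualities$completeness >= min_completeness, , drop = FALSE]
}
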