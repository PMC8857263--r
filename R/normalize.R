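#' Normalize binned read counts to copy ratios
#'
#' Divides each bin count by the sample median count (taken over bins with
#' at least one read), so the profile is centered at 1 and invariant to
#' sequencing depth: `normalize_counts(c * x)` equals
#' `normalize_counts(x)` for any positive scalar `c`.
#'
#' @param raw a `bin_counts` object.
#' @return A `normalized_profile`: list with `grid`, per-bin `ratio`
#'   (median 1), `sample_id`, `analyte`.
#' @examples
#' g <- make_genome(10, 1, seed = 1)
#' cl <- simulate_clone(g)
#' x <- simulate_cell_counts(cl, mean_depth = 50, seed = 1)
#' normalize_counts(x)$ratio
#' @export
normalize_counts <- function(raw) {
  stopifnot(inherits(raw, "bin_counts"))
  x <- raw$counts
  if (sum(x) <= 0) {
    stop("cannot normalize an all-zero count profile", call. = FALSE)
  }
  med <- median(x[x > 0])
  structure(list(grid = raw$grid, ratio = x / med,
                 sample_id = raw$sample_id, analyte = raw$analyte),
            class = "normalized_profile")
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf(
    "normalized_profile '%s' (%s): %d bins, ratio range [%.3f, %.3f]\n",
    x$sample_id, x$analyte, length(x$ratio), min(x$ratio), max(x$ratio)))
  invisible(x)
}
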