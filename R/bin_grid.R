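#' Construct an abstract binned genome
#'
#' Partitions a genome of `n_bins` equal bins into `n_chromosomes`
#' chromosomes whose sizes are drawn at random (deterministically for a
#' fixed seed) and sum exactly to `n_bins`. Coordinates are in bin units,
#' 0-based half-open, restarting at 0 on each chromosome. The grid is
#' abstract: bins, not base pairs — real-genome coordinates are a labeling
#' concern that plays no role in any computation downstream.
#'
#' @param n_bins total number of bins (>= n_chromosomes).
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param seed integer seed; the same arguments and seed always give the
#'   same grid.
#' @return A `bin_grid` object: a data.frame with columns `chrom`, `start`,
#'   `end` (one row per bin) and attributes `n_bins` and `chrom_table`
#'   (chromosome name, first 0-based bin index, length in bins).
#' @examples
#' g <- make_genome(5000, 22, seed = 1)
#' nrow(g)            # 5000
#' attr(g, "chrom_table")
#' @export
make_genome <- function(n_bins, n_chromosomes, seed = NULL) {
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes", min = 1L)
  if (n_bins < n_chromosomes) {
    stop("`n_bins` must be >= `n_chromosomes`", call. = FALSE)
  }
  sizes <- with_seed(seed, {
    if (n_chromosomes == 1L) {
      n_bins
    } else {
      # human-like decreasing size profile; +1 guarantees every
      # chromosome is non-empty while the total stays exact
      w <- (seq_len(n_chromosomes))^-0.6
      extra <- as.vector(rmultinom(1L, n_bins - n_chromosomes, prob = w))
      extra + 1L
    }
  })
  chrom <- paste0("chr", seq_len(n_chromosomes))
  grid <- data.frame(
    chrom = rep(chrom, sizes),
    start = unlist(lapply(sizes, function(s) seq_len(s) - 1L)),
    stringsAsFactors = FALSE
  )
  grid$end <- grid$start + 1L
  attr(grid, "n_bins") <- n_bins
  attr(grid, "chrom_table") <- data.frame(
    chrom = chrom,
    first_bin = cumsum(c(0L, sizes[-n_chromosomes])),
    n_bins = sizes,
    stringsAsFactors = FALSE
  )
  class(grid) <- c("bin_grid", "data.frame")
  grid
}

#' @export
print.bin_grid <- function(x, ...) {
  ct <- attr(x, "chrom_table")
  cat(sprintf("bin_grid: %d bins over %d chromosomes\n",
              attr(x, "n_bins"), nrow(ct)))
  cat(sprintf("  sizes: %s\n", paste(ct$n_bins, collapse = ", ")))
  invisible(x)
}

# Index ranges (1-based, R convention) of a chromosome's bins in the
# genome-ordered vectors carried alongside a grid.
chrom_bin_index <- function(grid, chrom) {
  ct <- attr(grid, "chrom_table")
  row <- ct[ct$chrom == chrom, , drop = FALSE]
  if (nrow(row) != 1L) stop(sprintf("unknown chromosome '%s'", chrom),
                            call. = FALSE)
  seq.int(row$first_bin + 1L, row$first_bin + row$n_bins)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(attr(a, "n_bins"), attr(b, "n_bins"))) &&
    identical(attr(a, "chrom_table")$chrom, attr(b, "chrom_table")$chrom) &&
    identical(attr(a, "chrom_table")$n_bins, attr(b, "chrom_table")$n_bins)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!grids_identical(a, b)) {
    stop("objects are defined on different bin grids", call. = FALSE)
  }
  invisible(TRUE)
}
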