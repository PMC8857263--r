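# Heatmap representation of multiple CNA profiles: hierarchical
# clustering of cells (columns) over genome-ordered bins (rows), with
# values coded in three levels against the gain/loss call limits.

#' Cluster CNA profiles for heatmap display
#'
#' Columns (cells) are clustered by Ward's minimum-variance method
#' ("ward.D") on Euclidean distances between per-bin log2 segmented
#' values; leaf order comes from the dendrogram, with input columns
#' pre-sorted by `sample_id` so equal profiles order lexicographically.
#' Per-bin values are coded `"loss"` / `"neutral"` / `"gain"` against the
#' same limits as [call_alterations()].
#'
#' @param profiles list of `segmented_profile`s on one grid (>= 1; a
#'   single profile yields a one-column matrix and no tree).
#' @param upper,lower tri-level coding limits (defaults 1.25 / 0.75,
#'   inclusive).
#' @return A `heatmap_matrix`: list with `codes` (character matrix, bins
#'   x cells, genome order x leaf order), `values` (numeric per-bin
#'   matrix in the same order), `linkage` (an `hclust` tree or NULL),
#'   `grid`.
#' @export
cluster_profiles <- function(profiles, upper = 1.25, lower = 0.75) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, TRUE, "segmented_profile")))
  grid <- profiles[[1L]]$grid
  for (p in profiles[-1L]) stop_if_grid_mismatch(grid, p$grid)
  ids <- vapply(profiles, `[[`, "", "sample_id")
  ord0 <- order(ids)
  profiles <- profiles[ord0]
  ids <- ids[ord0]
  vals <- vapply(profiles, `[[`, numeric(attr(grid, "n_bins")), "per_bin")
  colnames(vals) <- ids
  if (length(profiles) == 1L) {
    linkage <- NULL
    leaf_order <- 1L
  } else {
    lv <- log2(pmax(vals, 1e-6))
    linkage <- hclust(dist(t(lv), method = "euclidean"),
                      method = "ward.D")
    leaf_order <- linkage$order
  }
  vals <- vals[, leaf_order, drop = FALSE]
  codes <- matrix("neutral", nrow(vals), ncol(vals),
                  dimnames = dimnames(vals))
  codes[vals >= upper] <- "gain"
  codes[vals <= lower] <- "loss"
  structure(list(codes = codes, values = vals, linkage = linkage,
                 grid = grid, upper = upper, lower = lower),
            class = "heatmap_matrix")
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat(sprintf("heatmap_matrix: %d bins x %d cells (%d gain, %d loss entries)\n",
              nrow(x$codes), ncol(x$codes),
              sum(x$codes == "gain"), sum(x$codes == "loss")))
  invisible(x)
}

#' Export a heatmap matrix as TSV and PNG
#'
#' Writes the tri-level codes to `tsv_path` (rows = bins with `chrom`,
#' `start`, `end` columns; one column per cell in leaf order) and, when
#' `png_path` is given, a raster image with the conventional coloring:
#' neutral white, gain red, loss blue, one pixel column per cell
#' (widened by `scale`) and one pixel row per bin.
#'
#' @param matrix a `heatmap_matrix`.
#' @param tsv_path output TSV.
#' @param png_path optional output PNG.
#' @param scale integer pixel width per cell column (default 8).
#' @return Invisibly, the paths written.
#' @export
heatmap_export <- function(matrix, tsv_path, png_path = NULL, scale = 8L) {
  stopifnot(inherits(matrix, "heatmap_matrix"))
  df <- data.frame(chrom = matrix$grid$chrom, start = matrix$grid$start,
                   end = matrix$grid$end, matrix$codes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_commented(df, tsv_path,
                      list(n_cells = ncol(matrix$codes),
                           upper = matrix$upper, lower = matrix$lower))
  paths <- tsv_path
  if (!is.null(png_path)) {
    cols <- c(neutral = "#FFFFFF", gain = "#D73027", loss = "#4575B4")
    rgb <- col2rgb(cols[matrix$codes]) / 255
    n_bin <- nrow(matrix$codes)
    n_cell <- ncol(matrix$codes)
    img <- array(0, dim = c(n_bin, n_cell, 3L))
    for (ch in 1:3) {
      img[, , ch] <- matrix(rgb[ch, ], n_bin, n_cell)
    }
    if (scale > 1L) {
      img <- img[, rep(seq_len(n_cell), each = scale), , drop = FALSE]
    }
    png::writePNG(img, png_path)
    paths <- c(paths, png_path)
  }
  invisible(paths)
}

#' Read a heatmap TSV back into code form
#'
#' Inverse of the TSV half of [heatmap_export()].
#'
#' @param path a heatmap TSV.
#' @return A list with `codes` (matrix) and the bin coordinate columns.
#' @export
read_heatmap_tsv <- function(path) {
  df <- read_tsv_commented(path)
  coord <- df[, c("chrom", "start", "end")]
  codes <- as.matrix(df[, setdiff(names(df), c("chrom", "start", "end")),
                        drop = FALSE])
  list(codes = codes, coordinates = coord)
}
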