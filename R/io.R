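# Plain-text readers and writers. Every writer emits one '#' comment line
# carrying provenance (sample, analyte, parameters) so a file is
# self-describing; readers skip it.

#' Write binned read counts as TSV
#'
#' Columns: `chrom`, `start`, `end`, `count` (bin-unit, 0-based half-open
#' coordinates), preceded by one `#` header line with sample metadata.
#'
#' @param x a `bin_counts` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bin_counts <- function(x, path) {
  stopifnot(inherits(x, "bin_counts"))
  df <- data.frame(chrom = x$grid$chrom, start = x$grid$start,
                   end = x$grid$end, count = x$counts)
  write_tsv_commented(df, path, list(sample_id = x$sample_id,
                                     analyte = x$analyte,
                                     n_bins = length(x$counts)))
}

#' Read binned read counts from TSV
#'
#' Inverse of [write_bin_counts()]. Chromosome structure is rebuilt from
#' the `chrom` column (bins must be grouped by chromosome in file order).
#'
#' @param path a TSV written by [write_bin_counts()].
#' @param sample_id,analyte metadata for the rebuilt object.
#' @return A `bin_counts` object.
#' @export
read_bin_counts <- function(path, sample_id = basename(path),
                            analyte = "single_cell") {
  df <- read_tsv_commented(path)
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(df)))
  r <- rle(df$chrom)
  grid <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                     stringsAsFactors = FALSE)
  attr(grid, "n_bins") <- nrow(df)
  attr(grid, "chrom_table") <- data.frame(
    chrom = r$values,
    first_bin = cumsum(c(0L, r$lengths[-length(r$lengths)])),
    n_bins = r$lengths,
    stringsAsFactors = FALSE
  )
  class(grid) <- c("bin_grid", "data.frame")
  structure(list(grid = grid, counts = as.integer(df$count),
                 sample_id = sample_id, analyte = analyte),
            class = "bin_counts")
}

#' Write a slide cell table as TSV
#' @param x a `slide_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_slide_table <- function(x, path) {
  stopifnot(inherits(x, "slide_table"))
  write_tsv_commented(as.data.frame(x), path,
                      list(slide_nucleated_count =
                             attr(x, "slide_nucleated_count")))
}

#' Write a draw series (and its per-draw VAF tables) as TSV
#'
#' The draw table goes to `path`; when any draw has a VAF table, a long
#' companion table (`gene`, `protein_change`, `draw`, `vaf_percent`) is
#' written next to it with suffix `.vaf.tsv`.
#'
#' @param x a `draw_series`.
#' @param path output file for the draw table.
#' @return `path`, invisibly.
#' @export
write_draw_series <- function(x, path) {
  stopifnot(inherits(x, "draw_series"))
  write_tsv_commented(x$draws, path, list(patient_id = x$patient_id,
                                          template = x$template))
  vaf <- do.call(rbind, lapply(seq_along(x$vaf_tables), function(i) {
    t <- x$vaf_tables[[i]]
    if (is.null(t)) return(NULL)
    cbind(t[c("gene", "protein_change")], draw = i,
          vaf_percent = t$vaf_percent)
  }))
  if (!is.null(vaf)) {
    write_tsv_commented(vaf, sub("\\.tsv$", "", path) |>
                          paste0(".vaf.tsv"),
                        list(patient_id = x$patient_id))
  }
  invisible(path)
}

#' Write a segmented profile in IGV SEG format
#'
#' One row per segment: `sample`, `chrom`, `start`, `end` (bin units,
#' 0-based half-open), `n_bins`, `seg_mean` — the log2 of the segment mean
#' copy ratio. Round-trips through [read_seg()] to 6 decimals.
#'
#' @param profile a `segmented_profile` from [segment_profile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_seg <- function(profile, path) {
  stopifnot(inherits(profile, "segmented_profile"))
  seg <- profile$segments
  df <- data.frame(sample = profile$sample_id,
                   chrom = seg$chrom,
                   start = seg$start_bin,
                   end = seg$end_bin,
                   n_bins = seg$end_bin - seg$start_bin,
                   seg_mean = round(log2(pmax(seg$seg_mean, 1e-6)), 6))
  write_tsv_commented(df, path, list(sample_id = profile$sample_id,
                                     analyte = profile$analyte))
}

#' Read an IGV SEG file written by [write_seg()]
#'
#' Rebuilds a `segmented_profile` (segment table plus per-bin values on
#' the ratio scale). The grid is reconstructed from the segment spans.
#'
#' @param path a SEG file.
#' @return A `segmented_profile`.
#' @export
read_seg <- function(path) {
  df <- read_tsv_commented(path)
  stopifnot(all(c("sample", "chrom", "start", "end", "seg_mean")
                %in% names(df)))
  segs <- data.frame(chrom = df$chrom, start_bin = df$start,
                     end_bin = df$end, seg_mean = 2^df$seg_mean,
                     stringsAsFactors = FALSE)
  chroms <- unique(df$chrom)
  sizes <- vapply(chroms, function(ch) max(df$end[df$chrom == ch]), 0)
  grid <- data.frame(
    chrom = rep(chroms, sizes),
    start = unlist(lapply(sizes, function(s) seq_len(s) - 1L)),
    stringsAsFactors = FALSE)
  grid$end <- grid$start + 1L
  attr(grid, "n_bins") <- nrow(grid)
  attr(grid, "chrom_table") <- data.frame(
    chrom = chroms, first_bin = cumsum(c(0L, sizes[-length(sizes)])),
    n_bins = as.integer(sizes), stringsAsFactors = FALSE)
  class(grid) <- c("bin_grid", "data.frame")
  per_bin <- numeric(nrow(grid))
  ct <- attr(grid, "chrom_table")
  for (k in seq_len(nrow(segs))) {
    first <- ct$first_bin[ct$chrom == segs$chrom[k]]
    idx <- first + seq.int(segs$start_bin[k] + 1L, segs$end_bin[k])
    per_bin[idx] <- segs$seg_mean[k]
  }
  structure(list(grid = grid, segments = segs, per_bin = per_bin,
                 sample_id = df$sample[1L], analyte = "unknown"),
            class = "segmented_profile")
}
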