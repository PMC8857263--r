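# Circular binary segmentation of normalized bin-count profiles.
#
# Each chromosome is split recursively at the arc maximizing the pooled
# two-sample t-statistic on log2 ratios; a split is accepted when its
# permutation p-value is below alpha. An undo pass then re-merges adjacent
# segments whose log2 means differ by less than undo_sd estimated
# bin-level noise SDs, suppressing spurious splits that survive the
# permutation test. Segment means are reported on the ratio scale as the
# arithmetic mean of the member bins, so segmentation preserves each
# chromosome's mean ratio exactly.

# Recursively collect 0-based changepoints strictly inside (0, n).
cbs_recurse <- function(y, min_width, alpha, n_perm, t_accept,
                        offset = 0L) {
  n <- length(y)
  if (n < 2L * min_width) return(integer())
  sp <- .cbs_split(y, min_width, n_perm, alpha, t_accept)
  if (is.na(sp$t) || sp$p >= alpha) return(integer())
  i <- sp$i
  j <- sp$j
  cuts <- integer()
  if (i > 0L) cuts <- c(cuts, offset + i)
  if (j < n) cuts <- c(cuts, offset + j)
  pieces <- rbind(c(0L, i), c(i, j), c(j, n))
  for (r in seq_len(nrow(pieces))) {
    a <- pieces[r, 1L]
    b <- pieces[r, 2L]
    if (b - a >= 2L * min_width) {
      cuts <- c(cuts, cbs_recurse(y[(a + 1L):b], min_width, alpha, n_perm,
                                  t_accept, offset + a))
    }
  }
  sort(unique(cuts))
}

# Merge adjacent segments whose log2 means differ by < threshold,
# smallest difference first, recomputing means after every merge.
undo_merge <- function(bounds, y_log, threshold) {
  repeat {
    if (length(bounds) <= 2L) return(bounds)
    k <- length(bounds) - 1L
    means <- vapply(seq_len(k), function(s) {
      mean(y_log[(bounds[s] + 1L):bounds[s + 1L]])
    }, 0)
    d <- abs(diff(means))
    if (!length(d) || min(d) >= threshold) return(bounds)
    drop <- which.min(d) + 1L   # interior boundary between the pair
    bounds <- bounds[-drop]
  }
}

#' Segment a normalized profile into constant copy-ratio segments
#'
#' Circular binary segmentation: within each chromosome, the arc of bins
#' maximizing the two-sample t-statistic (log2 ratios, pooled variance)
#' against the rest of the chromosome is tested by permutation and the
#' split accepted when p < `alpha`; accepted pieces are segmented
#' recursively. An undo rule then re-merges adjacent segments whose log2
#' means differ by less than `undo_sd` times the bin-level noise SD
#' (estimated as `mad(diff(log2 ratio)) / sqrt(2)` over the whole sample).
#' Segments never cross chromosome boundaries; a chromosome shorter than
#' `2 * min_width` is returned as a single segment.
#'
#' @param norm a `normalized_profile` from [normalize_counts()].
#' @param alpha permutation significance level for accepting a split
#'   (default 0.01).
#' @param min_width minimum segment width in bins (default 5, >= 2).
#' @param n_perm permutations per split test (default 1000; the test
#'   stops early once non-significance is guaranteed).
#' @param undo_sd undo threshold in noise-SD units (default 1; 0 disables
#'   the undo pass).
#' @param t_accept t-statistic beyond which a split is accepted without
#'   permutations (default 10; the null maximum over all arcs
#'   concentrates around `sqrt(2 log n_pairs)`, about 5 at chromosome
#'   scale, so values past 10 have permutation p-value 0 in practice).
#' @param seed integer seed for the permutation stream; fixed seed gives
#'   identical segmentations.
#' @return A `segmented_profile`: list with `grid`, `segments` (data.frame
#'   `chrom`, `start_bin`, `end_bin` 0-based half-open within the
#'   chromosome, `n_bins`, `seg_mean` on the ratio scale), `per_bin`
#'   (each bin's segment mean), `sample_id`, `analyte`.
#' @examples
#' g <- make_genome(60, 1, seed = 1)
#' cl <- simulate_clone(g, data.frame(chrom = "chr1", start_bin = 30,
#'                                    end_bin = 60, ratio = 0.5))
#' x <- simulate_cell_counts(cl, mean_depth = 200, dispersion = Inf,
#'                           seed = 1)
#' segment_profile(normalize_counts(x), seed = 1)$segments
#' @export
segment_profile <- function(norm, alpha = 0.01, min_width = 5L,
                            n_perm = 1000L, undo_sd = 1, t_accept = 10,
                            seed = NULL) {
  stopifnot(inherits(norm, "normalized_profile"))
  check_fraction(alpha, "alpha")
  min_width <- check_count(min_width, "min_width", min = 2L)
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  ratio <- pmax(norm$ratio, 1e-6)   # zero-count bins floored before log
  y_log_all <- log2(ratio)
  noise_sd <- mad(diff(y_log_all)) / sqrt(2)
  ct <- attr(norm$grid, "chrom_table")
  with_seed(seed, {
    seg_list <- vector("list", nrow(ct))
    per_bin <- numeric(length(ratio))
    for (c_i in seq_len(nrow(ct))) {
      idx <- chrom_bin_index(norm$grid, ct$chrom[c_i])
      y <- y_log_all[idx]
      n <- length(y)
      cuts <- cbs_recurse(y, min_width, alpha, n_perm, t_accept)
      bounds <- c(0L, cuts, n)
      if (undo_sd > 0 && noise_sd > 0) {
        bounds <- undo_merge(bounds, y, undo_sd * noise_sd)
      }
      k <- length(bounds) - 1L
      means <- vapply(seq_len(k), function(s) {
        mean(ratio[idx[(bounds[s] + 1L):bounds[s + 1L]]])
      }, 0)
      seg_list[[c_i]] <- data.frame(
        chrom = ct$chrom[c_i],
        start_bin = bounds[-(k + 1L)],
        end_bin = bounds[-1L],
        n_bins = diff(bounds),
        seg_mean = means,
        stringsAsFactors = FALSE)
      per_bin[idx] <- rep(means, diff(bounds))
    }
    structure(list(grid = norm$grid,
                   segments = do.call(rbind, seg_list),
                   per_bin = per_bin,
                   sample_id = norm$sample_id,
                   analyte = norm$analyte),
              class = "segmented_profile")
  })
}

#' @export
print.segmented_profile <- function(x, ...) {
  cat(sprintf("segmented_profile '%s' (%s): %d bins, %d segments\n",
              x$sample_id, x$analyte, length(x$per_bin),
              nrow(x$segments)))
  invisible(x)
}

# Build a segmented_profile directly from a clone's true ratios (one
# segment per constant run). Used where a noiseless reference is wanted.
as_segmented_profile <- function(clone) {
  stopifnot(inherits(clone, "clone_profile"))
  ct <- attr(clone$grid, "chrom_table")
  seg_list <- lapply(seq_len(nrow(ct)), function(c_i) {
    idx <- chrom_bin_index(clone$grid, ct$chrom[c_i])
    r <- rle(clone$ratio[idx])
    ends <- cumsum(r$lengths)
    data.frame(chrom = ct$chrom[c_i],
               start_bin = c(0L, ends[-length(ends)]),
               end_bin = ends,
               n_bins = r$lengths,
               seg_mean = r$values,
               stringsAsFactors = FALSE)
  })
  structure(list(grid = clone$grid, segments = do.call(rbind, seg_list),
                 per_bin = clone$ratio, sample_id = clone$clone_id,
                 analyte = "truth"),
            class = "segmented_profile")
}
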