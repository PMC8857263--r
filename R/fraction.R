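# CTC-referenced estimation of the tumor-derived fraction of cfDNA.
#
# The read depth behind an alteration in cfDNA is proportional to the
# depth over the same region in the reference tumor profile: if a clone
# contributes a fraction f of the cfDNA, a segment with reference ratio r
# appears in cfDNA at (1 - f) + f * r. Inverting per segment gives
# f_s = (r_cf - 1) / (r_ref - 1); segments are combined by the median for
# robustness to outlying segments.

#' Informative segments of a tumor reference profile
#'
#' Segments whose mean copy ratio deviates from 1 by at least
#' `min_deviation` — i.e. segments at or beyond the 1.25/0.75 alteration
#' limits for the default 0.25 — carry a usable copy-number signal for
#' fraction estimation; neutral segments are uninformative.
#'
#' @param reference a `segmented_profile` or `clone_profile` (a clone is
#'   converted to its exact segment runs).
#' @param min_deviation minimum |ratio - 1| (default 0.25).
#' @return A data.frame of informative segments (`chrom`, `start_bin`,
#'   `end_bin`, `n_bins`, `seg_mean`); may have zero rows.
#' @export
informative_segments <- function(reference, min_deviation = 0.25) {
  if (inherits(reference, "clone_profile")) {
    reference <- as_segmented_profile(reference)
  }
  stopifnot(inherits(reference, "segmented_profile"))
  check_positive(min_deviation, "min_deviation")
  seg <- reference$segments
  seg[abs(seg$seg_mean - 1) >= min_deviation, , drop = FALSE]
}

# mean of a profile's per-bin values over one reference segment
segment_mean_over <- function(per_bin, grid, seg_row) {
  idx <- chrom_bin_index(grid, seg_row$chrom)
  mean(per_bin[idx[(seg_row$start_bin + 1L):seg_row$end_bin]])
}

#' Estimate the tumor fraction of cfDNA against a CTC reference
#'
#' For each informative reference segment s, the per-segment fraction is
#' `f_s = (r_cf(s) - 1) / (r_ref(s) - 1)`, where `r_cf(s)` is the mean
#' cfDNA copy ratio over the segment's bins and `r_ref(s)` its reference
#' ratio. The estimate is the median of the `f_s`, clamped to \[0, 1\];
#' a percentile bootstrap over segments gives the confidence interval.
#' Estimates below the 5% confidence floor are flagged (`below_floor`)
#' rather than suppressed.
#'
#' @param cfdna a `normalized_profile` or `segmented_profile` of the
#'   cfDNA sample (per-bin values are averaged over reference segments,
#'   so cfDNA segmentation is optional).
#' @param reference a `clone_profile` or `segmented_profile` with at
#'   least one informative segment.
#' @param min_deviation informativeness threshold (default 0.25).
#' @param n_boot bootstrap resamples of the segment set (default 200).
#' @param floor confidence floor on the reported fraction (default 0.05).
#' @param seed integer seed for the bootstrap.
#' @return A `tumor_fraction_estimate`: list with `f_hat`,
#'   `per_segment_f` (unclamped, for diagnostics), `segments`,
#'   `n_informative`, `ci_low`, `ci_high`, `below_floor`.
#' @export
estimate_tumor_fraction <- function(cfdna, reference, min_deviation = 0.25,
                                    n_boot = 200L, floor = 0.05,
                                    seed = NULL) {
  per_bin <- if (inherits(cfdna, "segmented_profile")) cfdna$per_bin
             else if (inherits(cfdna, "normalized_profile")) cfdna$ratio
             else stop("`cfdna` must be a normalized or segmented profile",
                       call. = FALSE)
  ref_grid <- if (inherits(reference, "clone_profile")) reference$grid
              else reference$grid
  stop_if_grid_mismatch(cfdna$grid, ref_grid)
  info <- informative_segments(reference, min_deviation)
  if (!nrow(info)) {
    stop("reference has no informative segments: tumor fraction not estimable",
         call. = FALSE)
  }
  r_cf <- vapply(seq_len(nrow(info)), function(k) {
    segment_mean_over(per_bin, ref_grid, info[k, ])
  }, 0)
  f_s <- (r_cf - 1) / (info$seg_mean - 1)
  f_hat <- min(max(median(f_s), 0), 1)
  ci <- with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(f_s), replace = TRUE)
      min(max(median(f_s[idx]), 0), 1)
    }, 0)
    quantile(boots, c(0.025, 0.975), names = FALSE)
  })
  structure(list(f_hat = f_hat, per_segment_f = f_s, segments = info,
                 n_informative = nrow(info), ci_low = ci[1L],
                 ci_high = ci[2L], below_floor = f_hat < floor,
                 floor = floor),
            class = "tumor_fraction_estimate")
}

#' @export
print.tumor_fraction_estimate <- function(x, ...) {
  cat(sprintf(
    "tumor fraction: %.3f (95%% CI %.3f-%.3f, %d informative segment(s))%s\n",
    x$f_hat, x$ci_low, x$ci_high, x$n_informative,
    if (x$below_floor) sprintf(" [below %.0f%% confidence floor]",
                               100 * x$floor) else ""))
  invisible(x)
}

#' Longitudinal tumor-fraction report
#'
#' Tabulates per-draw estimates with their confidence intervals, the
#' confidence-floor flag, and the draw-over-draw change in fraction.
#'
#' @param estimates list of `tumor_fraction_estimate`s in draw order, or
#'   a numeric vector of fractions.
#' @param draw_index optional draw labels (default 1..n).
#' @param floor confidence floor used when `estimates` is numeric.
#' @return A data.frame with one row per draw: `draw_index`, `f_hat`,
#'   `ci_low`, `ci_high`, `below_floor`, `change` (NA for the first
#'   draw).
#' @export
fraction_report <- function(estimates, draw_index = NULL, floor = 0.05) {
  if (is.numeric(estimates)) {
    estimates <- lapply(estimates, function(f) {
      list(f_hat = f, ci_low = NA_real_, ci_high = NA_real_,
           below_floor = f < floor)
    })
  }
  stopifnot(length(estimates) >= 1L)
  n <- length(estimates)
  if (is.null(draw_index)) draw_index <- seq_len(n)
  f <- vapply(estimates, `[[`, 0, "f_hat")
  data.frame(
    draw_index = draw_index,
    f_hat = f,
    ci_low = vapply(estimates, `[[`, 0, "ci_low"),
    ci_high = vapply(estimates, `[[`, 0, "ci_high"),
    below_floor = vapply(estimates, `[[`, TRUE, "below_floor"),
    change = c(NA_real_, diff(f)))
}
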