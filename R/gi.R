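# Genomic instability scoring and gain/loss alteration calling.

#' Ratio to the median (RM)
#'
#' Divides a vector of per-bin values by its median, so the rescaled
#' vector has median exactly 1 and is invariant to any positive scaling
#' of the input. The RM vector is the argument of the GI score.
#'
#' @param values per-bin positive values (at least one must be positive;
#'   zeros are floored at 1e-6 downstream).
#' @return The RM vector, same length as `values`.
#' @export
ratio_to_median <- function(values) {
  if (!length(values) || all(values <= 0) || !all(is.finite(values))) {
    stop("`values` must contain at least one positive finite value",
         call. = FALSE)
  }
  values / median(values)
}

# per-bin GI contribution; 0 at RM = 1, saturates at 1 + tanh(2),
# symmetric in RM <-> 1/RM
gi_bin_contribution <- function(rm) {
  tanh(3 * abs(log(pmax(rm, 1e-6))) - 2) + tanh(2)
}

#' Genomic instability (GI) score of a segmented profile
#'
#' Sums, over all bins, `tanh(3 * |log(RM)| - 2) + tanh(2)` where RM is
#' the segmented per-bin value re-expressed as a ratio to its median
#' (natural log; the score is identical for a gain RM = r and the
#' mirror-image loss RM = 1/r). A perfectly flat profile scores exactly
#' 0; each bin's contribution saturates at `1 + tanh(2)` as RM moves away
#' from 1, so the score is bounded by `n_bins * (1 + tanh(2))`. The score
#' is computed on segmented per-bin values — segmentation suppresses the
#' bin-level noise that would otherwise inflate a copy-neutral profile
#' far beyond the neutral band.
#'
#' @param profile a `segmented_profile` (or any object with a `per_bin`
#'   numeric field).
#' @return A `gi_score`: list with `value`, `n_bins`, and `band`
#'   (`"neutral"` for value <= 30, `"aberrant"` for value > 100,
#'   `"intermediate"` between).
#' @examples
#' rm <- c(rep(1, 90), rep(2, 10))
#' sum(tanh(3 * abs(log(rm)) - 2) + tanh(2))  # the score by hand
#' @export
gi_score <- function(profile) {
  v <- if (is.list(profile)) profile$per_bin else profile
  if (is.null(v) || !length(v)) {
    stop("profile carries no per-bin values", call. = FALSE)
  }
  rm <- ratio_to_median(pmax(v, 1e-6))
  value <- sum(gi_bin_contribution(rm))
  structure(list(value = value, n_bins = length(v),
                 band = classify_gi(value)),
            class = "gi_score")
}

#' @export
print.gi_score <- function(x, ...) {
  cat(sprintf("GI score: %.2f over %d bins [%s]\n",
              x$value, x$n_bins, x$band))
  invisible(x)
}

#' Classify a GI score into its interpretive band
#'
#' A copy-neutral profile scores at most 30 (`"neutral"`, inclusive); a
#' cell carrying a few chromosomal breaks typically scores above 100
#' (`"aberrant"`, exclusive); anything between is `"intermediate"`.
#'
#' @param value a non-negative GI score.
#' @return `"neutral"`, `"intermediate"` or `"aberrant"`.
#' @export
classify_gi <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value < 0) {
    stop("`value` must be a single non-negative number", call. = FALSE)
  }
  if (value <= 30) "neutral" else if (value > 100) "aberrant" else
    "intermediate"
}

#' Call copy-number gains and losses from a segmented profile
#'
#' A segment is a gain when its mean copy ratio is at or above `upper`
#' (default 1.25) and a loss when at or below `lower` (default 0.75);
#' both limits are inclusive. Neutral segments are not listed.
#'
#' @param profile a `segmented_profile`.
#' @param upper,lower call limits, `lower < 1 < upper`.
#' @return An `alteration_calls`: list with `sample_id`, `calls`
#'   (data.frame `chrom`, `start_bin`, `end_bin`, `direction`,
#'   `seg_mean`), `upper`, `lower`, and the originating `grid`.
#' @export
call_alterations <- function(profile, upper = 1.25, lower = 0.75) {
  stopifnot(inherits(profile, "segmented_profile"))
  if (!(lower < 1 && 1 < upper)) {
    stop("require `lower` < 1 < `upper`", call. = FALSE)
  }
  seg <- profile$segments
  direction <- ifelse(seg$seg_mean >= upper, "gain",
                      ifelse(seg$seg_mean <= lower, "loss", NA))
  keep <- !is.na(direction)
  calls <- data.frame(chrom = seg$chrom[keep],
                      start_bin = seg$start_bin[keep],
                      end_bin = seg$end_bin[keep],
                      direction = direction[keep],
                      seg_mean = seg$seg_mean[keep],
                      stringsAsFactors = FALSE)
  structure(list(sample_id = profile$sample_id, calls = calls,
                 upper = upper, lower = lower, grid = profile$grid),
            class = "alteration_calls")
}

#' @export
print.alteration_calls <- function(x, ...) {
  cat(sprintf("alteration_calls '%s': %d gain(s), %d loss(es) at limits [%.2f, %.2f]\n",
              x$sample_id, sum(x$calls$direction == "gain"),
              sum(x$calls$direction == "loss"), x$lower, x$upper))
  if (nrow(x$calls)) print(x$calls)
  invisible(x)
}
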