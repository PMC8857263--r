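#' Define a clone by its copy-number events
#'
#' Builds the ground-truth copy-ratio profile of a tumor clone from an
#' explicit event list. Ratios are relative to diploid: 1 is neutral, 0.5 a
#' one-copy loss, 1.5 a one-copy gain. Bins not covered by any event are
#' exactly 1; later events overwrite earlier ones where they overlap.
#'
#' @param grid a [make_genome()] grid.
#' @param events data.frame (or list of lists) with columns
#'   `chrom`, `start_bin`, `end_bin` (0-based half-open, within the
#'   chromosome) and `ratio` (> 0). May be empty for a neutral clone.
#' @param clone_id label for the clone.
#' @return A `clone_profile`: list with `grid`, per-bin `ratio`, `clone_id`
#'   and the `events` table.
#' @examples
#' g <- make_genome(100, 2, seed = 1)
#' cl <- simulate_clone(g, data.frame(chrom = "chr1", start_bin = 0,
#'                                    end_bin = 10, ratio = 0.5))
#' @export
simulate_clone <- function(grid, events = NULL, clone_id = "clone1") {
  stopifnot(inherits(grid, "bin_grid"))
  ratio <- rep(1, attr(grid, "n_bins"))
  if (is.null(events)) {
    events <- data.frame(chrom = character(), start_bin = integer(),
                         end_bin = integer(), ratio = numeric())
  }
  if (!is.data.frame(events)) events <- do.call(rbind.data.frame, events)
  if (nrow(events)) {
    ct <- attr(grid, "chrom_table")
    for (k in seq_len(nrow(events))) {
      ev <- events[k, ]
      row <- ct[ct$chrom == ev$chrom, , drop = FALSE]
      if (nrow(row) != 1L) {
        stop(sprintf("event %d: unknown chromosome '%s'", k, ev$chrom),
             call. = FALSE)
      }
      if (ev$start_bin < 0 || ev$end_bin > row$n_bins ||
          ev$start_bin >= ev$end_bin) {
        stop(sprintf("event %d: bins [%d, %d) out of bounds for %s (%d bins)",
                     k, ev$start_bin, ev$end_bin, ev$chrom, row$n_bins),
             call. = FALSE)
      }
      if (!is.finite(ev$ratio) || ev$ratio <= 0) {
        stop(sprintf("event %d: ratio must be > 0", k), call. = FALSE)
      }
      idx <- row$first_bin + seq.int(ev$start_bin + 1L, ev$end_bin)
      ratio[idx] <- ev$ratio
    }
  }
  structure(list(grid = grid, ratio = ratio, clone_id = clone_id,
                 events = events),
            class = "clone_profile")
}

#' @export
print.clone_profile <- function(x, ...) {
  cat(sprintf("clone_profile '%s': %d bins, %d event(s), %d altered bin(s)\n",
              x$clone_id, length(x$ratio), nrow(x$events),
              sum(x$ratio != 1)))
  invisible(x)
}

# negative-binomial draw that degrades gracefully to Poisson at
# dispersion = Inf (size parameterization: var = mu + mu^2/size)
rnb <- function(n, mu, size) {
  if (is.infinite(size)) rpois(n, lambda = mu) else
    rnbinom(n, mu = mu, size = size)
}

#' Simulate single-cell binned read counts
#'
#' Draws one count per bin from a negative binomial with mean
#' `mean_depth * true_ratio` and the given dispersion (`size`
#' parameterization, so variance = mu + mu^2/dispersion). The dispersion
#' stands in for whole-genome-amplification noise on top of shallow
#' sequencing; `dispersion = Inf` gives Poisson counts.
#'
#' @param clone a [simulate_clone()] profile.
#' @param mean_depth expected reads per neutral bin (default 50, the
#'   package's single-cell convention).
#' @param dispersion negative-binomial size; default 10 (WGA-noisy cells).
#' @param seed integer seed; identical arguments and seed give identical
#'   counts.
#' @param sample_id label for the sample.
#' @return A `bin_counts` object: list with `grid`, integer `counts`,
#'   `sample_id`, `analyte = "single_cell"`.
#' @export
simulate_cell_counts <- function(clone, mean_depth = 50, dispersion = 10,
                                 seed = NULL, sample_id = clone$clone_id) {
  stopifnot(inherits(clone, "clone_profile"))
  check_positive(mean_depth, "mean_depth")
  check_positive(dispersion, "dispersion", allow_inf = TRUE)
  counts <- with_seed(seed,
    rnb(length(clone$ratio), mu = mean_depth * clone$ratio,
        size = dispersion))
  structure(list(grid = clone$grid, counts = as.integer(counts),
                 sample_id = sample_id, analyte = "single_cell"),
            class = "bin_counts")
}

#' Simulate cfDNA binned read counts as a tumor/background mixture
#'
#' cfDNA is modeled as a mixture of copy-neutral background (weight
#' `1 - tumor_fraction`) and one or more tumor clones (weight
#' `tumor_fraction`, split among clones by `weights`). The expected per-bin
#' copy ratio is `(1 - f) + f * sum(w_c * ratio_c)`; counts are then
#' negative binomial as in [simulate_cell_counts()].
#'
#' @param clones list of `clone_profile`s sharing one grid.
#' @param weights clone weights, summing to 1 (default equal).
#' @param tumor_fraction fraction f of cfDNA that is tumor-derived, in
#'   \[0, 1\].
#' @param mean_depth expected reads per neutral bin (default 100).
#' @param dispersion negative-binomial size; default 50 (cfDNA is cleaner
#'   than amplified single cells).
#' @param seed integer seed.
#' @param sample_id label.
#' @return A `bin_counts` object with `analyte = "cfdna"` and attribute
#'   `expected_ratio`, the analytic per-bin mixture ratio used as the
#'   negative-binomial mean (divided by depth).
#' @export
simulate_cfdna_counts <- function(clones, weights = NULL, tumor_fraction,
                                  mean_depth = 100, dispersion = 50,
                                  seed = NULL, sample_id = "cfdna") {
  if (inherits(clones, "clone_profile")) clones <- list(clones)
  stopifnot(length(clones) >= 1L,
            all(vapply(clones, inherits, TRUE, "clone_profile")))
  f <- check_fraction(tumor_fraction, "tumor_fraction")
  check_positive(mean_depth, "mean_depth")
  check_positive(dispersion, "dispersion", allow_inf = TRUE)
  if (is.null(weights)) weights <- rep(1 / length(clones), length(clones))
  if (length(weights) != length(clones) ||
      abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    stop("`weights` must be non-negative and sum to 1", call. = FALSE)
  }
  grid <- clones[[1L]]$grid
  for (cl in clones[-1L]) stop_if_grid_mismatch(grid, cl$grid)
  clone_mix <- Reduce(`+`, Map(function(cl, w) w * cl$ratio,
                               clones, weights))
  expected <- (1 - f) + f * clone_mix
  counts <- with_seed(seed,
    rnb(length(expected), mu = mean_depth * expected, size = dispersion))
  structure(list(grid = grid, counts = as.integer(counts),
                 sample_id = sample_id, analyte = "cfdna"),
            class = "bin_counts",
            expected_ratio = expected)
}

#' @export
print.bin_counts <- function(x, ...) {
  cat(sprintf("bin_counts '%s' (%s): %d bins, total %d reads\n",
              x$sample_id, x$analyte, length(x$counts),
              sum(x$counts)))
  invisible(x)
}

#' Simulate a stained-slide cell feature table
#'
#' Emulates the per-cell feature table produced by immunofluorescence
#' scanning of an enrichment-free slide: white blood cells (WBCs) form the
#' background population and candidate CTCs are shifted upward in the
#' tumor-marker channels (CK, ER). All four channel intensities are drawn
#' from a normal distribution truncated at zero; cell coordinates are
#' uniform on a 1000 x 1000 frame. No images are simulated, only the
#' feature rows that downstream morphometry consumes.
#'
#' @param n_ctc number of CTC rows (>= 0).
#' @param n_wbc number of WBC rows (>= 1).
#' @param ctc_intensity_shift additive shift of CTC CK/ER intensity over
#'   the WBC background mean, in intensity units.
#' @param bg_mean,bg_sd background channel intensity mean and SD
#'   (`bg_sd > 0`).
#' @param seed integer seed.
#' @param slide_nucleated_count total nucleated cells on the slide
#'   (defaults to `n_ctc + n_wbc`; real slides carry millions, used by
#'   [volume_analyzed()]).
#' @return A `slide_table`: data.frame with columns `cell_id`, `class`,
#'   `frame_x`, `frame_y`, `ck`, `er`, `cd45`, `dapi`, `nuclear_area`,
#'   `nuclear_eccentricity`, plus attribute `slide_nucleated_count`.
#' @export
simulate_slide <- function(n_ctc, n_wbc, ctc_intensity_shift = 0,
                           bg_mean = 100, bg_sd = 10, seed = NULL,
                           slide_nucleated_count = n_ctc + n_wbc) {
  n_ctc <- check_count(n_ctc, "n_ctc", min = 0L)
  n_wbc <- check_count(n_wbc, "n_wbc", min = 1L)
  check_positive(bg_sd, "bg_sd")
  n <- n_ctc + n_wbc
  tab <- with_seed(seed, {
    cls <- c(rep("CTC", n_ctc), rep("WBC", n_wbc))
    trunc0 <- function(m, s, k) pmax(rnorm(k, m, s), 0)
    shift <- ifelse(cls == "CTC", ctc_intensity_shift, 0)
    data.frame(
      cell_id = sprintf("cell%04d", seq_len(n)),
      class = cls,
      frame_x = runif(n, 0, 1000),
      frame_y = runif(n, 0, 1000),
      ck   = pmax(trunc0(bg_mean, bg_sd, n) + shift, 0),
      er   = pmax(trunc0(bg_mean, bg_sd, n) + shift, 0),
      cd45 = trunc0(bg_mean, bg_sd, n),
      dapi = trunc0(bg_mean, bg_sd, n),
      nuclear_area = rlnorm(n, meanlog = log(50), sdlog = 0.3),
      nuclear_eccentricity = pmin(rbeta(n, 2, 2), 1 - 1e-9),
      stringsAsFactors = FALSE
    )
  })
  attr(tab, "slide_nucleated_count") <- slide_nucleated_count
  class(tab) <- c("slide_table", "data.frame")
  tab
}

# Bundled longitudinal scenarios. CTCs/ml trajectories echo the response
# archetypes seen clinically: a poor responder rises monotonically from
# tens of CTCs/ml; a best responder spikes once then returns below
# 1.5 CTCs/ml; an average responder oscillates at low counts; "flat" is
# the zero-CTC control. VAF schedules list, per variant, the draws at
# which the assay reports it and its VAF (%).
draw_series_templates <- function() {
  list(
    poor_responder = list(
      days = c(0, 51),
      ctc_per_ml = c(37, 52),
      vaf = data.frame(
        gene = c("ESR1", "PIK3CA", "TP53", "ERBB2", "PIK3CA"),
        protein_change = c("E380Q", "E545K", "R248Q", "L755S", "E726K"),
        draw = c("1,2", "1,2", "1,2", "2", "2"),
        vaf_percent = c("0.50,0.07", "2.7,30", "0.31,0.19", "0.13", "0.09"),
        stringsAsFactors = FALSE
      )
    ),
    best_responder = list(
      days = c(0, 56, 112, 168, 224, 280),
      ctc_per_ml = c(0.5, 1.0, 220, 0.5, 1.2, 0.8),
      vaf = data.frame(
        gene = "TP53", protein_change = "R213*",
        draw = "1,2,3,4,5,6",
        vaf_percent = "0.08,0.2,0.47,1.1,2.91,4.5",
        stringsAsFactors = FALSE
      )
    ),
    average_responder = list(
      days = c(0, 60, 120, 180),
      ctc_per_ml = c(1.9, 2.1, 10.9, 1.0),
      vaf = data.frame(
        gene = "ERBB2", protein_change = "G776V",
        draw = "3,4", vaf_percent = "0.5,1.94",
        stringsAsFactors = FALSE
      )
    ),
    flat = list(
      days = c(0, 60, 120),
      ctc_per_ml = c(0, 0, 0),
      vaf = NULL
    )
  )
}

#' Simulate a longitudinal draw series for a patient scenario
#'
#' Generates an ordered series of peripheral-blood draws (8-12 week
#' intervals) following one of the bundled response templates:
#' `"poor_responder"` (monotone-increasing CTCs/ml), `"best_responder"`
#' (a spike that resolves below 1.5 CTCs/ml), `"average_responder"`,
#' or `"flat"` (no CTCs). Analyzed volume per draw is derived from a
#' realistic WBC concentration and slide cell load; CTC counts are the
#' template rate times the analyzed volume with multiplicative jitter.
#' Variant (VAF) tables follow each template's acquired/lost schedule
#' exactly and are not jittered.
#'
#' @param template one of the template names above.
#' @param patient_id label.
#' @param seed integer seed.
#' @param jitter_sd lognormal SD of the multiplicative CTC-count jitter
#'   (default 0.05; set 0 for the template's exact trajectory).
#' @return A `draw_series`: list with `patient_id`, a `draws` data.frame
#'   (`draw_index`, `day`, `n_ctc_detected`, `slide_nucleated_count`,
#'   `wbc_per_ml`, `ctc_per_ml`) and `vaf_tables`, a per-draw list of VAF
#'   data.frames (or NULL when no assay was run at that draw).
#' @export
simulate_draw_series <- function(template, patient_id = template,
                                 seed = NULL, jitter_sd = 0.05) {
  tpl <- draw_series_templates()[[template]]
  if (is.null(tpl)) {
    stop(sprintf("unknown template '%s'; available: %s", template,
                 paste(names(draw_series_templates()), collapse = ", ")),
         call. = FALSE)
  }
  n <- length(tpl$days)
  with_seed(seed, {
    wbc_per_ml <- round(runif(n, 4e6, 8e6))
    slide_nucleated <- round(runif(n, 2.5e6, 3.5e6))
    volume <- slide_nucleated / wbc_per_ml
    jit <- if (jitter_sd > 0) rlnorm(n, 0, jitter_sd) else rep(1, n)
    target <- tpl$ctc_per_ml * jit
    # poor responder must stay monotone increasing despite jitter
    if (template == "poor_responder") target <- sort(target)
    n_ctc <- round(target * volume)
    draws <- data.frame(
      draw_index = seq_len(n),
      day = tpl$days,
      n_ctc_detected = as.integer(n_ctc),
      slide_nucleated_count = slide_nucleated,
      wbc_per_ml = wbc_per_ml,
      ctc_per_ml = n_ctc / volume,
      stringsAsFactors = FALSE
    )
    vaf_tables <- rep(list(NULL), n)
    if (!is.null(tpl$vaf)) {
      for (k in seq_len(nrow(tpl$vaf))) {
        dr <- as.integer(strsplit(tpl$vaf$draw[k], ",")[[1L]])
        vf <- as.numeric(strsplit(tpl$vaf$vaf_percent[k], ",")[[1L]])
        for (i in seq_along(dr)) {
          row <- data.frame(gene = tpl$vaf$gene[k],
                            protein_change = tpl$vaf$protein_change[k],
                            vaf_percent = vf[i], stringsAsFactors = FALSE)
          vaf_tables[[dr[i]]] <- rbind(vaf_tables[[dr[i]]], row)
        }
      }
    }
    structure(list(patient_id = patient_id, draws = draws,
                   vaf_tables = vaf_tables, template = template),
              class = "draw_series")
  })
}

#' @export
print.draw_series <- function(x, ...) {
  cat(sprintf("draw_series '%s' (%s): %d draws over %d days\n",
              x$patient_id, x$template, nrow(x$draws), max(x$draws$day)))
  print(x$draws)
  invisible(x)
}
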