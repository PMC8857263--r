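# End-to-end runs: configuration, the simulation study behind the
# package's calibration claims, and per-patient report bundles.

#' Default run configuration
#'
#' Collects every tunable threshold of the pipeline in one serializable
#' list. All the interpretive constants — call limits 1.25/0.75, GI bands
#' 30/100, kinetics stability 5 CTCs/ml, positivity 1 CTC/ml, the 5%
#' fraction confidence floor, the 2-cells/2-alterations clonality rule —
#' live here, never hard-coded at call sites.
#'
#' @param ... named overrides of any default, nested lists merged
#'   shallowly per section (e.g. `segmentation = list(alpha = 0.05)`).
#' @param seed integer seed recorded in the config.
#' @return A `run_config` list.
#' @export
lb_config <- function(..., seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    genome = list(n_bins = 5000L, n_chromosomes = 22L),
    noise = list(cell_depth = 50, cell_dispersion = 10,
                 cfdna_depth = 100, cfdna_dispersion = 50),
    segmentation = list(alpha = 0.01, min_width = 5L, n_perm = 1000L,
                        undo_sd = 1),
    calls = list(upper = 1.25, lower = 0.75),
    gi = list(neutral_max = 30, aberrant_min = 100),
    clones = list(min_shared = 2L, min_cells = 2L,
                  min_reciprocal_overlap = 0.5),
    fraction = list(min_deviation = 0.25, n_boot = 200L, floor = 0.05),
    ctc = list(positivity = 1, stability = 5, sdom_k = 50L)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @return `read_config` returns a `run_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(lb_config, c(cfg[setdiff(names(cfg), "seed")],
                       seed = cfg$seed))
}

# standard scenario clone: events on the first chromosomes of the grid,
# arm-scale, alternating loss/gain
scenario_clone <- function(grid, n_events = 2L, span = 0.45,
                           clone_id = "sim_clone") {
  ct <- attr(grid, "chrom_table")
  stopifnot(n_events <= nrow(ct))
  events <- do.call(rbind, lapply(seq_len(n_events), function(k) {
    width <- max(2L, floor(ct$n_bins[k] * span))
    data.frame(chrom = ct$chrom[k], start_bin = 0L, end_bin = width,
               ratio = if (k %% 2L) 0.5 else 1.5,
               stringsAsFactors = FALSE)
  }))
  simulate_clone(grid, events, clone_id = clone_id)
}

#' Run the package's calibration simulation study
#'
#' Three experiment families, all driven by the configuration:
#' `"gi_neutral"` — copy-neutral single cells, scored after
#' normalization and segmentation, checked against the neutral band;
#' `"gi_aberrant"` — cells carrying a few arm-scale single-copy events,
#' checked against the aberrant band; `"fraction"` — cfDNA mixtures over
#' a grid of true tumor fractions, recovered with the CTC-referenced
#' estimator. Results come back as one tidy data.frame; identical
#' configurations produce identical tables.
#'
#' @param config a [lb_config()] list.
#' @param n_seeds replicates per condition (default 20).
#' @param fractions tumor-fraction grid for the recovery experiment
#'   (default `c(0.1, 0.3, 0.63)`).
#' @param n_aberrant_events arm-scale events for the aberrant arm
#'   (default 2).
#' @param experiments subset of the three family names to run.
#' @param out optional path: the tidy table is written there as TSV.
#' @return A data.frame with columns `experiment`, `condition`,
#'   `replicate`, `value` (GI score or estimated fraction), `truth`
#'   (NA or the true fraction), `pass` (the per-replicate band or
#'   recovery check).
#' @export
run_simulation_study <- function(config = lb_config(), n_seeds = 20L,
                                 fractions = c(0.1, 0.3, 0.63),
                                 n_aberrant_events = 2L,
                                 experiments = c("gi_neutral",
                                                 "gi_aberrant",
                                                 "fraction"),
                                 out = NULL) {
  stopifnot(inherits(config, "run_config"))
  experiments <- match.arg(experiments, several.ok = TRUE)
  grid <- make_genome(config$genome$n_bins, config$genome$n_chromosomes,
                      seed = config$seed)
  seg_args <- config$segmentation
  gi_of <- function(counts, seed) {
    seg <- segment_profile(normalize_counts(counts),
                           alpha = seg_args$alpha,
                           min_width = seg_args$min_width,
                           n_perm = seg_args$n_perm,
                           undo_sd = seg_args$undo_sd, seed = seed)
    gi_score(seg)$value
  }
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)
  if ("gi_neutral" %in% experiments) {
    neutral <- simulate_clone(grid, clone_id = "neutral")
    for (r in seq_len(n_seeds)) {
      s <- config$seed + 1000L + r
      gi <- gi_of(simulate_cell_counts(neutral,
                                       config$noise$cell_depth,
                                       config$noise$cell_dispersion,
                                       seed = s), seed = s)
      add(experiment = "gi_neutral", condition = "neutral",
          replicate = r, value = gi, truth = NA_real_,
          pass = gi <= config$gi$neutral_max)
    }
  }
  if ("gi_aberrant" %in% experiments) {
    aberrant <- scenario_clone(grid, n_events = n_aberrant_events,
                               clone_id = "aberrant")
    for (r in seq_len(n_seeds)) {
      s <- config$seed + 2000L + r
      gi <- gi_of(simulate_cell_counts(aberrant,
                                       config$noise$cell_depth,
                                       config$noise$cell_dispersion,
                                       seed = s), seed = s)
      add(experiment = "gi_aberrant",
          condition = sprintf("%d_events", n_aberrant_events),
          replicate = r, value = gi, truth = NA_real_,
          pass = gi > config$gi$aberrant_min)
    }
  }
  if ("fraction" %in% experiments) {
    ref <- scenario_clone(grid, n_events = 4L, clone_id = "reference")
    for (f in fractions) {
      for (r in seq_len(n_seeds)) {
        s <- config$seed + 3000L + round(10000 * f) + r
        cf <- simulate_cfdna_counts(list(ref), tumor_fraction = f,
                                    mean_depth = config$noise$cfdna_depth,
                                    dispersion =
                                      config$noise$cfdna_dispersion,
                                    seed = s)
        est <- estimate_tumor_fraction(
          normalize_counts(cf), ref,
          min_deviation = config$fraction$min_deviation,
          n_boot = config$fraction$n_boot, seed = s)
        add(experiment = "fraction", condition = sprintf("f=%.2f", f),
            replicate = r, value = est$f_hat, truth = f,
            pass = abs(est$f_hat - f) <= 0.05)
      }
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out)) {
    write_tsv_commented(res, out, list(seed = config$seed,
                                       n_seeds = n_seeds))
  }
  res
}

#' Generate a per-patient liquid-biopsy report bundle
#'
#' Writes the longitudinal view of one patient to a directory: the
#' CTCs/ml timeline with kinetics labels, the GI trajectory, the
#' tumor-fraction trajectory, the variant trajectory table and, when
#' segmented profiles are supplied, the clone heatmap (TSV + PNG).
#' Missing inputs are skipped and listed in the returned manifest;
#' regeneration into the same directory is idempotent.
#'
#' @param series a `draw_series`.
#' @param out_dir output directory (created if needed).
#' @param profiles optional list of `segmented_profile`s (CTCs) for the
#'   heatmap.
#' @param gi_values optional per-draw GI scores.
#' @param fraction_estimates optional list of
#'   `tumor_fraction_estimate`s (or numeric fractions) per draw.
#' @param config a [lb_config()] for thresholds.
#' @return Invisibly, a manifest list: `written` (paths) and `missing`
#'   (names of skipped sections).
#' @export
generate_patient_report <- function(series, out_dir, profiles = NULL,
                                    gi_values = NULL,
                                    fraction_estimates = NULL,
                                    config = lb_config()) {
  stopifnot(inherits(series, "draw_series"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  missing <- character()
  pth <- function(f) file.path(out_dir, f)

  timeline <- series$draws
  if (nrow(timeline) >= 2L) {
    kin <- classify_kinetics(timeline$ctc_per_ml,
                             threshold = config$ctc$stability)
    timeline$kinetics <- c(NA, kin$label)
  } else {
    timeline$kinetics <- NA_character_
  }
  timeline$positive <- timeline$ctc_per_ml >= config$ctc$positivity
  if (!is.null(gi_values)) {
    timeline$gi <- gi_values
    timeline$gi_band <- vapply(gi_values, classify_gi, "")
  }
  write_tsv_commented(timeline, pth("timeline.tsv"),
                      list(patient_id = series$patient_id))
  written <- c(written, pth("timeline.tsv"))

  if (!is.null(fraction_estimates)) {
    fr <- fraction_report(fraction_estimates,
                          draw_index = seq_along(fraction_estimates),
                          floor = config$fraction$floor)
    write_tsv_commented(fr, pth("fraction.tsv"),
                        list(patient_id = series$patient_id))
    written <- c(written, pth("fraction.tsv"))
  } else {
    missing <- c(missing, "fraction")
  }

  traj <- track_variants(series$vaf_tables)
  traj$vaf <- NULL   # list column: long form is written instead
  write_tsv_commented(traj, pth("variants.tsv"),
                      list(patient_id = series$patient_id))
  written <- c(written, pth("variants.tsv"))

  if (!is.null(profiles) && length(profiles) >= 1L) {
    hm <- cluster_profiles(profiles, upper = config$calls$upper,
                           lower = config$calls$lower)
    heatmap_export(hm, pth("heatmap.tsv"), pth("heatmap.png"))
    written <- c(written, pth("heatmap.tsv"), pth("heatmap.png"))
  } else {
    missing <- c(missing, "heatmap")
  }
  invisible(list(written = written, missing = missing))
}
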