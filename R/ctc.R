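# Cellular-fraction analytics: enumeration, kinetics, morphometry,
# longitudinal variant tracking.

#' Blood volume analyzed by a slide
#'
#' The analyzed whole-blood volume is inferred from cell counts: the
#' number of nucleated cells detected on the slide divided by the
#' patient's measured WBC concentration.
#'
#' @param slide_nucleated_count nucleated cells detected on the slide.
#' @param wbc_per_ml WBC concentration of the whole blood (cells/ml).
#' @return Volume in ml.
#' @examples
#' volume_analyzed(3e6, 6e6)  # 0.5 ml
#' @export
volume_analyzed <- function(slide_nucleated_count, wbc_per_ml) {
  check_positive(slide_nucleated_count, "slide_nucleated_count")
  check_positive(wbc_per_ml, "wbc_per_ml")
  slide_nucleated_count / wbc_per_ml
}

#' Enumerate CTCs on a slide as CTCs/ml
#'
#' Counts every CTC-class cell individually — members of a cluster each
#' count, never the cluster as one entity — and divides by the analyzed
#' volume from [volume_analyzed()]. A sample is positive when it reaches
#' 1 CTC/ml (inclusive).
#'
#' @param slide a `slide_table` (its `slide_nucleated_count` attribute
#'   supplies the cell load), or any data.frame with a `class` column
#'   plus an explicit `slide_nucleated_count` argument.
#' @param wbc_per_ml WBC concentration (cells/ml).
#' @param slide_nucleated_count override for the slide's nucleated-cell
#'   count.
#' @param draw_index,day optional draw metadata carried through.
#' @return A `ctc_timepoint`: list with `draw_index`, `day`, `n_ctc`,
#'   `volume_ml`, `ctc_per_ml`, `positive`.
#' @export
enumerate_ctc <- function(slide, wbc_per_ml,
                          slide_nucleated_count =
                            attr(slide, "slide_nucleated_count"),
                          draw_index = NA_integer_, day = NA_real_) {
  stopifnot(is.data.frame(slide), "class" %in% names(slide))
  if (is.null(slide_nucleated_count)) {
    stop("`slide_nucleated_count` is required (attribute or argument)",
         call. = FALSE)
  }
  vol <- volume_analyzed(slide_nucleated_count, wbc_per_ml)
  n_ctc <- sum(slide$class == "CTC")
  rate <- n_ctc / vol
  structure(list(draw_index = draw_index, day = day, n_ctc = n_ctc,
                 volume_ml = vol, ctc_per_ml = rate,
                 positive = rate >= 1),
            class = "ctc_timepoint")
}

#' @export
print.ctc_timepoint <- function(x, ...) {
  cat(sprintf("ctc_timepoint: %d CTC(s) in %.3f ml = %.2f CTCs/ml [%s]\n",
              x$n_ctc, x$volume_ml, x$ctc_per_ml,
              if (x$positive) "positive" else "negative"))
  invisible(x)
}

#' Classify CTC kinetics between consecutive draws
#'
#' Each consecutive pair of CTCs/ml values is labeled `"stable"` when the
#' change is smaller than 5 CTCs/ml in absolute value (exclusive),
#' `"increasing"` for a change of at least +5, `"decreasing"` for at
#' most -5.
#'
#' @param ctc_per_ml ordered CTCs/ml values (>= 2 draws).
#' @param threshold stability threshold (default 5 CTCs/ml).
#' @return A data.frame with one row per interval: `from`, `to`, `delta`,
#'   `label`.
#' @examples
#' classify_kinetics(c(37.08, 52.49))  # increasing
#' @export
classify_kinetics <- function(ctc_per_ml, threshold = 5) {
  if (!is.numeric(ctc_per_ml) || length(ctc_per_ml) < 2L) {
    stop("need at least 2 draws to classify kinetics", call. = FALSE)
  }
  delta <- diff(ctc_per_ml)
  label <- ifelse(abs(delta) < threshold, "stable",
                  ifelse(delta > 0, "increasing", "decreasing"))
  data.frame(from = head(seq_along(ctc_per_ml), -1L),
             to = tail(seq_along(ctc_per_ml), -1L),
             delta = delta, label = label,
             stringsAsFactors = FALSE)
}

#' SDOM channel intensity of a cell against its WBC background
#'
#' The Standard Deviation Over the Mean: the cell's channel intensity
#' expressed in standard-deviation units of the background formed by the
#' `k` white blood cells nearest to it in frame coordinates (Euclidean
#' distance, ties broken by `cell_id`):
#' `SDOM = (I_cell - mean(I_bg)) / sd(I_bg)`. When fewer than `k` WBCs
#' exist on the slide all of them are used and the result carries
#' attribute `background_short = TRUE`.
#'
#' @param cell a single row of the slide table (the cell of interest).
#' @param slide the full `slide_table` (>= 2 WBCs).
#' @param channel one of `"ck"`, `"er"`, `"cd45"`, `"dapi"`.
#' @param k background size (default 50).
#' @return The signed SDOM value, with attributes `n_background` and
#'   `background_short`.
#' @export
sdom <- function(cell, slide, channel = "ck", k = 50L) {
  stopifnot(is.data.frame(slide), nrow(cell) == 1L,
            channel %in% names(slide))
  wbc <- slide[slide$class == "WBC" & slide$cell_id != cell$cell_id, ,
               drop = FALSE]
  if (nrow(wbc) < 2L) {
    stop("need at least 2 WBCs on the slide for a background",
         call. = FALSE)
  }
  d <- sqrt((wbc$frame_x - cell$frame_x)^2 +
              (wbc$frame_y - cell$frame_y)^2)
  ord <- order(d, wbc$cell_id)
  n_bg <- min(k, nrow(wbc))
  bg <- wbc[[channel]][ord[seq_len(n_bg)]]
  s <- sd(bg)
  if (s == 0) {
    stop("degenerate background: zero intensity variance", call. = FALSE)
  }
  structure((cell[[channel]] - mean(bg)) / s,
            n_background = n_bg,
            background_short = n_bg < k)
}

#' Morphometric records for every CTC on a slide
#'
#' Applies [sdom()] to each CTC for the requested channels and carries
#' the nuclear area and eccentricity through.
#'
#' @param slide a `slide_table`.
#' @param channels channels to score (default CK and ER).
#' @param k SDOM background size (default 50).
#' @return A data.frame, one row per CTC: `cell_id`, `nuclear_area`,
#'   `nuclear_eccentricity`, one `sdom_<channel>` column per channel,
#'   and `n_background`.
#' @export
morphometrics <- function(slide, channels = c("ck", "er"), k = 50L) {
  ctc <- slide[slide$class == "CTC", , drop = FALSE]
  out <- ctc[, c("cell_id", "nuclear_area", "nuclear_eccentricity"),
             drop = FALSE]
  for (ch in channels) {
    out[[paste0("sdom_", ch)]] <- vapply(seq_len(nrow(ctc)), function(i) {
      as.numeric(sdom(ctc[i, ], slide, channel = ch, k = k))
    }, 0)
  }
  out$n_background <- vapply(seq_len(nrow(ctc)), function(i) {
    attr(sdom(ctc[i, ], slide, channel = channels[1L], k = k),
         "n_background")
  }, 0L)
  rownames(out) <- NULL
  out
}

#' Track variant trajectories across longitudinal draws
#'
#' Builds one trajectory per distinct variant (gene + protein change)
#' from per-draw VAF tables. Status is determined by presence at the
#' first and last analyzed draws: present at both = `"persistent"`;
#' absent first, present last = `"acquired"`; present first, absent
#' last = `"lost"`; present only at interior draws = `"transient"`.
#' "Absent" means not reported by the assay at that draw — never VAF 0.
#' With a single draw every reported variant is `"persistent"` by
#' convention. Trajectories seen at two or more draws with strictly
#' increasing VAF carry `monotone_increase = TRUE`.
#'
#' @param tables list of per-draw VAF data.frames (columns `gene`,
#'   `protein_change`, `vaf_percent`); NULL entries mark draws without
#'   assay results and are skipped.
#' @param draw_index optional labels for the analyzed draws.
#' @return A data.frame, one row per variant: `gene`, `protein_change`,
#'   `status`, `first_draw`, `last_draw`, `n_draws_present`,
#'   `first_vaf`, `last_vaf`, `monotone_increase`, plus a `vaf` list
#'   column of per-draw VAFs (NA where absent).
#' @export
track_variants <- function(tables, draw_index = NULL) {
  analyzed <- !vapply(tables, is.null, TRUE)
  if (is.null(draw_index)) draw_index <- seq_along(tables)
  tables <- tables[analyzed]
  draw_index <- draw_index[analyzed]
  if (!length(tables)) {
    return(data.frame(gene = character(), protein_change = character(),
                      status = character()))
  }
  n_draw <- length(tables)
  long <- do.call(rbind, lapply(seq_len(n_draw), function(i) {
    t <- tables[[i]]
    stopifnot(all(c("gene", "protein_change", "vaf_percent") %in% names(t)))
    if (!nrow(t)) return(NULL)
    data.frame(gene = t$gene, protein_change = t$protein_change,
               pos = i, vaf = t$vaf_percent, stringsAsFactors = FALSE)
  }))
  if (is.null(long)) {
    return(data.frame(gene = character(), protein_change = character(),
                      status = character()))
  }
  key <- paste(long$gene, long$protein_change)
  variants <- unique(key)   # first-appearance order: draw, then row
  rows <- lapply(variants, function(v) {
    sel <- long[key == v, , drop = FALSE]
    vaf <- rep(NA_real_, n_draw)
    vaf[sel$pos] <- sel$vaf
    present <- !is.na(vaf)
    pf <- present[1L]
    pl <- present[n_draw]
    status <- if (n_draw == 1L) "persistent"
      else if (pf && pl) "persistent"
      else if (!pf && pl) "acquired"
      else if (pf && !pl) "lost"
      else "transient"
    pv <- vaf[present]
    data.frame(gene = sel$gene[1L], protein_change = sel$protein_change[1L],
               status = status,
               first_draw = draw_index[which(present)[1L]],
               last_draw = draw_index[rev(which(present))[1L]],
               n_draws_present = sum(present),
               first_vaf = pv[1L], last_vaf = pv[length(pv)],
               monotone_increase = length(pv) >= 2L && all(diff(pv) > 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$vaf <- lapply(variants, function(v) {
    sel <- long[key == v, , drop = FALSE]
    vaf <- rep(NA_real_, n_draw)
    vaf[sel$pos] <- sel$vaf
    setNames(vaf, draw_index)
  })
  rownames(out) <- NULL
  out
}
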