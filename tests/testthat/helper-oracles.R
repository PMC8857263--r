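# Independent oracles and small fixture builders. Everything here is
# deliberately written by a different route than the package code: the
# segmentation oracle uses stats::t.test over an explicit double loop,
# clone components use igraph, pairing uses exhaustive enumeration.

# Exhaustive max-t arc search over one chromosome of log ratios, with the
# same admissibility rules as the segmentation (both groups >= min_width,
# non-empty flanks >= min_width). Returns 0-based changepoints (i, j).
oracle_max_t <- function(y, min_width = 5L) {
  n <- length(y)
  best <- list(t = -Inf, i = NA_integer_, j = NA_integer_)
  for (i in 0:(n - min_width)) {
    if (i != 0 && i < min_width) next
    for (j in (i + min_width):n) {
      k <- j - i
      m <- n - k
      if (m < min_width) break
      if (j != n && n - j < min_width) next
      if (j == n && i > 0) next   # duplicate of the prefix arc (0, i)
      arc <- y[(i + 1):j]
      rest <- y[-((i + 1):j)]
      tt <- if (sd(arc) == 0 && sd(rest) == 0) {
        if (mean(arc) == mean(rest)) 0 else Inf
      } else {
        abs(unname(stats::t.test(arc, rest, var.equal = TRUE)$statistic))
      }
      if (tt > best$t) best <- list(t = tt, i = i, j = j)
    }
  }
  best
}

# Best 2-changepoint partition of y (0-based cuts a < b) by residual sum
# of squares over the three pieces, each >= min_width.
oracle_two_changepoints <- function(y, min_width = 5L) {
  n <- length(y)
  best <- list(rss = Inf, a = NA_integer_, b = NA_integer_)
  for (a in min_width:(n - 2 * min_width)) {
    for (b in (a + min_width):(n - min_width)) {
      pieces <- list(y[1:a], y[(a + 1):b], y[(b + 1):n])
      rss <- sum(vapply(pieces, function(p) sum((p - mean(p))^2), 0))
      if (rss < best$rss) best <- list(rss = rss, a = a, b = b)
    }
  }
  best
}

# Clone partition via igraph connected components.
oracle_clone_partition <- function(shared, min_shared = 2L,
                                   min_cells = 2L) {
  adj <- (shared >= min_shared) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  ifelse(sizes[as.character(comp)] >= min_cells, comp, NA)
}

# Exhaustive one-to-one pairing count between two call tables under the
# same admissibility rule as shared_alterations.
oracle_pairing_count <- function(ca, cb, min_recip = 0.5) {
  admissible <- list()
  for (i in seq_len(nrow(ca))) {
    for (j in seq_len(nrow(cb))) {
      if (ca$chrom[i] != cb$chrom[j]) next
      if (ca$direction[i] != cb$direction[j]) next
      ov <- min(ca$end_bin[i], cb$end_bin[j]) -
        max(ca$start_bin[i], cb$start_bin[j])
      if (ov <= 0) next
      la <- ca$end_bin[i] - ca$start_bin[i]
      lb <- cb$end_bin[j] - cb$start_bin[j]
      if (min(ov / la, ov / lb) >= min_recip) {
        admissible[[length(admissible) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(admissible)) return(0L)
  best <- 0L
  recurse <- function(idx, used_a, used_b, count) {
    if (idx > length(admissible)) {
      best <<- max(best, count)
      return()
    }
    p <- admissible[[idx]]
    if (!(p[1] %in% used_a) && !(p[2] %in% used_b)) {
      recurse(idx + 1L, c(used_a, p[1]), c(used_b, p[2]), count + 1L)
    }
    recurse(idx + 1L, used_a, used_b, count)
  }
  recurse(1L, integer(), integer(), 0L)
  best
}

# Build a normalized_profile directly from per-bin ratios (tests only).
make_norm <- function(grid, ratio, sample_id = "test") {
  structure(list(grid = grid, ratio = ratio, sample_id = sample_id,
                 analyte = "single_cell"),
            class = "normalized_profile")
}

# An alteration_calls object from an explicit call table (tests only).
make_calls <- function(grid, calls, sample_id = "cell") {
  structure(list(sample_id = sample_id, calls = calls,
                 upper = 1.25, lower = 0.75, grid = grid),
            class = "alteration_calls")
}

# A slide table with exactly known geometry/intensities (tests only).
make_slide <- function(df, nucleated = nrow(df)) {
  attr(df, "slide_nucleated_count") <- nucleated
  class(df) <- c("slide_table", "data.frame")
  df
}
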