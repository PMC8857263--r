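# Clone detection from shared copy-number alterations.

#' Count alterations shared between two cells
#'
#' Two calls match when they sit on the same chromosome, have the same
#' direction (gain with gain, loss with loss) and their bin spans overlap
#' reciprocally by at least `min_reciprocal_overlap` (the overlap must be
#' that fraction of *both* spans). Each call participates in at most one
#' match; candidate pairs are taken greedily by decreasing overlap, ties
#' toward the leftmost pair.
#'
#' @param a,b `alteration_calls` on the same grid.
#' @param min_reciprocal_overlap fraction in (0, 1\]; default 0.5.
#' @return The number of matched call pairs (symmetric in `a`, `b`).
#' @export
shared_alterations <- function(a, b, min_reciprocal_overlap = 0.5) {
  stopifnot(inherits(a, "alteration_calls"),
            inherits(b, "alteration_calls"))
  stop_if_grid_mismatch(a$grid, b$grid)
  check_fraction(min_reciprocal_overlap, "min_reciprocal_overlap")
  ca <- a$calls
  cb <- b$calls
  if (!nrow(ca) || !nrow(cb)) return(0L)
  # enumerate admissible pairs
  pairs <- expand.grid(ia = seq_len(nrow(ca)), ib = seq_len(nrow(cb)))
  keep <- ca$chrom[pairs$ia] == cb$chrom[pairs$ib] &
    ca$direction[pairs$ia] == cb$direction[pairs$ib]
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) return(0L)
  ov <- pmin(ca$end_bin[pairs$ia], cb$end_bin[pairs$ib]) -
    pmax(ca$start_bin[pairs$ia], cb$start_bin[pairs$ib])
  la <- ca$end_bin[pairs$ia] - ca$start_bin[pairs$ia]
  lb <- cb$end_bin[pairs$ib] - cb$start_bin[pairs$ib]
  recip <- pmin(ov / la, ov / lb)
  keep <- ov > 0 & recip >= min_reciprocal_overlap
  pairs <- pairs[keep, , drop = FALSE]
  recip <- recip[keep]
  if (!nrow(pairs)) return(0L)
  # greedy one-to-one matching: best overlap first, ties leftmost
  ord <- order(-recip, ca$start_bin[pairs$ia], cb$start_bin[pairs$ib])
  used_a <- logical(nrow(ca))
  used_b <- logical(nrow(cb))
  n_match <- 0L
  for (k in ord) {
    ia <- pairs$ia[k]
    ib <- pairs$ib[k]
    if (!used_a[ia] && !used_b[ib]) {
      used_a[ia] <- TRUE
      used_b[ib] <- TRUE
      n_match <- n_match + 1L
    }
  }
  n_match
}

#' Assign cells to clones by shared alterations
#'
#' Clonality: two or more cells sharing two or more genomic alterations.
#' A graph is built with an edge between every pair of cells whose
#' [shared_alterations()] count reaches `min_shared`; clones are the
#' connected components with at least `min_cells` members (transitive
#' closure of the pairwise rule). All remaining cells are `"unclonal"`.
#' Clone labels (`"clone1"`, `"clone2"`, ...) are ordered by each
#' component's first cell in input order, so the partition is stable
#' under input reordering.
#'
#' @param cells list of `alteration_calls` (named, or names taken from
#'   `sample_id`).
#' @param min_shared minimum shared alterations for an edge (default 2).
#' @param min_cells minimum component size for a clone (default 2).
#' @param min_reciprocal_overlap passed to [shared_alterations()].
#' @return A `clone_assignment`: list with `cells` (ids),
#'   `clone_labels` (per cell), `shared_counts` (symmetric matrix),
#'   `min_shared`, `min_cells`.
#' @export
assign_clones <- function(cells, min_shared = 2L, min_cells = 2L,
                          min_reciprocal_overlap = 0.5) {
  if (!length(cells)) {
    return(structure(list(cells = character(), clone_labels = character(),
                          shared_counts = matrix(0L, 0, 0),
                          min_shared = min_shared, min_cells = min_cells),
                     class = "clone_assignment"))
  }
  stopifnot(all(vapply(cells, inherits, TRUE, "alteration_calls")))
  ids <- names(cells)
  if (is.null(ids)) ids <- vapply(cells, `[[`, "", "sample_id")
  n <- length(cells)
  shared <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        s <- shared_alterations(cells[[i]], cells[[j]],
                                min_reciprocal_overlap)
        shared[i, j] <- s
        shared[j, i] <- s
      }
    }
  }
  # connected components over the >= min_shared adjacency (label
  # propagation via BFS; components discovered in input order)
  comp <- rep(NA_integer_, n)
  next_comp <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    next_comp <- next_comp + 1L
    queue <- s
    comp[s] <- next_comp
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(shared[v, ] >= min_shared & is.na(comp))
      comp[nb] <- next_comp
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp)
  labels <- rep("unclonal", n)
  clone_no <- 0L
  for (cmp in seq_len(next_comp)) {
    if (sizes[cmp] >= min_cells) {
      clone_no <- clone_no + 1L
      labels[comp == cmp] <- paste0("clone", clone_no)
    }
  }
  structure(list(cells = ids, clone_labels = setNames(labels, ids),
                 shared_counts = shared, min_shared = min_shared,
                 min_cells = min_cells),
            class = "clone_assignment")
}

#' @export
print.clone_assignment <- function(x, ...) {
  tab <- table(x$clone_labels)
  cat(sprintf("clone_assignment: %d cell(s), %d clone(s)\n",
              length(x$cells),
              sum(names(tab) != "unclonal")))
  print(tab)
  invisible(x)
}
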