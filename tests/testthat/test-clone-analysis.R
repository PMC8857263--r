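# Shared-alteration counting, clone assignment, heatmap clustering.

grid100 <- make_genome(100, 2, seed = 1)

calls_of <- function(tab, id) make_calls(grid100, tab, id)

test_that("shared_alterations counts direction-matched reciprocal overlaps", {
  three <- data.frame(chrom = "chr1",
                      start_bin = c(0L, 20L, 40L),
                      end_bin = c(10L, 30L, 50L),
                      direction = c("gain", "loss", "gain"),
                      seg_mean = c(1.5, 0.5, 1.6),
                      stringsAsFactors = FALSE)
  a <- calls_of(three, "a")
  expect_equal(shared_alterations(a, calls_of(three, "b")), 3)
  disjoint <- three
  disjoint$start_bin <- c(60L, 70L, 80L)
  disjoint$end_bin <- c(65L, 75L, 85L)
  expect_equal(shared_alterations(a, calls_of(disjoint, "b")), 0)
  flipped <- three
  flipped$direction <- c("loss", "gain", "loss")
  expect_equal(shared_alterations(a, calls_of(flipped, "b")), 0)
  # below-threshold reciprocal overlap does not match
  shifted <- three[1, ]
  shifted$start_bin <- 6L
  shifted$end_bin <- 16L   # overlap 4 of 10 = 40% < 50%
  expect_equal(shared_alterations(a, calls_of(shifted, "b")), 0)
  shifted$start_bin <- 4L
  shifted$end_bin <- 14L   # overlap 6 of 10 = 60%
  expect_equal(shared_alterations(a, calls_of(shifted, "b")), 1)
})

test_that("shared_alterations is symmetric and matches the exhaustive pairing oracle", {
  set.seed(5)
  random_calls <- function() {
    n <- sample(1:4, 1)
    starts <- sort(sample(seq(0, 80, by = 10), n))
    data.frame(chrom = "chr1", start_bin = starts,
               end_bin = starts + sample(5:15, n, replace = TRUE),
               direction = sample(c("gain", "loss"), n, replace = TRUE),
               seg_mean = 1, stringsAsFactors = FALSE)
  }
  for (rep in 1:20) {
    a <- calls_of(random_calls(), "a")
    b <- calls_of(random_calls(), "b")
    ab <- shared_alterations(a, b)
    expect_identical(ab, shared_alterations(b, a))
    expect_equal(ab, oracle_pairing_count(a$calls, b$calls))
  }
})

test_that("clonality requires two cells sharing two alterations", {
  sig <- data.frame(chrom = c("chr1", "chr2"),
                    start_bin = c(0L, 0L), end_bin = c(20L, 15L),
                    direction = c("gain", "loss"),
                    seg_mean = c(1.5, 0.5), stringsAsFactors = FALSE)
  a <- calls_of(sig, "a")
  b <- calls_of(sig, "b")
  asg <- assign_clones(list(a = a, b = b))
  expect_equal(unname(asg$clone_labels), c("clone1", "clone1"))
  # only one shared alteration: both unclonal
  one <- calls_of(sig[1, ], "c")
  asg1 <- assign_clones(list(a = a, c = one))
  expect_equal(unname(asg1$clone_labels), c("unclonal", "unclonal"))
  expect_equal(length(assign_clones(list())$cells), 0)
})

test_that("clones are transitive closures: A-B and B-C link A-C", {
  s1 <- data.frame(chrom = "chr1", start_bin = c(0L, 30L),
                   end_bin = c(20L, 50L), direction = c("gain", "loss"),
                   seg_mean = c(1.5, 0.5), stringsAsFactors = FALSE)
  s2 <- data.frame(chrom = "chr2", start_bin = c(0L, 20L),
                   end_bin = c(15L, 35L), direction = c("gain", "gain"),
                   seg_mean = c(1.5, 1.6), stringsAsFactors = FALSE)
  a <- calls_of(s1, "a")
  b <- calls_of(rbind(s1, s2), "b")   # shares 2 with a and 2 with c
  c_ <- calls_of(s2, "c")
  asg <- assign_clones(list(a = a, b = b, c = c_))
  expect_equal(shared_alterations(a, c_), 0)
  expect_equal(unname(asg$clone_labels), rep("clone1", 3))
})

test_that("clone assignment matches igraph components on random cell sets", {
  skip_if_not_installed("igraph")
  set.seed(9)
  sigs <- lapply(1:3, function(k) {
    starts <- sort(sample(seq(0, 80, by = 20), 2))
    data.frame(chrom = c("chr1", "chr2"), start_bin = starts,
               end_bin = starts + 10L,
               direction = sample(c("gain", "loss"), 2, replace = TRUE),
               seg_mean = 1, stringsAsFactors = FALSE)
  })
  for (rep in 1:10) {
    cells <- lapply(1:6, function(i) {
      calls_of(sigs[[sample(3, 1)]], paste0("cell", i))
    })
    names(cells) <- paste0("cell", 1:6)
    asg <- assign_clones(cells)
    orc <- oracle_clone_partition(asg$shared_counts)
    # same partition: clone co-membership agrees pairwise
    for (i in 1:5) for (j in (i + 1):6) {
      mine <- asg$clone_labels[i] != "unclonal" &&
        asg$clone_labels[i] == asg$clone_labels[j]
      theirs <- !is.na(orc[i]) && !is.na(orc[j]) && orc[i] == orc[j]
      expect_identical(mine, theirs)
    }
  }
})

test_that("clone assignment is permutation invariant", {
  sig <- data.frame(chrom = c("chr1", "chr2"), start_bin = c(0L, 0L),
                    end_bin = c(20L, 15L), direction = c("gain", "loss"),
                    seg_mean = 1, stringsAsFactors = FALSE)
  other <- data.frame(chrom = "chr2", start_bin = 40L, end_bin = 60L,
                      direction = "gain", seg_mean = 1.5,
                      stringsAsFactors = FALSE)
  cells <- list(a = calls_of(sig, "a"), b = calls_of(sig, "b"),
                x = calls_of(other, "x"))
  fwd <- assign_clones(cells)
  rev_ <- assign_clones(cells[c(3, 1, 2)])
  expect_equal(fwd$clone_labels[c("a", "b", "x")] != "unclonal",
               rev_$clone_labels[c("a", "b", "x")] != "unclonal")
  same_fwd <- fwd$clone_labels["a"] == fwd$clone_labels["b"]
  same_rev <- rev_$clone_labels["a"] == rev_$clone_labels["b"]
  expect_identical(unname(same_fwd), unname(same_rev))
})

test_that("ward clustering separates planted groups and keeps all columns", {
  g <- make_genome(200, 2, seed = 3)
  clA <- simulate_clone(g, data.frame(chrom = "chr1", start_bin = 0,
                                      end_bin = 60, ratio = 0.5), "A")
  clB <- simulate_clone(g, data.frame(chrom = "chr2", start_bin = 0,
                                      end_bin = 50, ratio = 1.5), "B")
  profs <- c(
    lapply(1:5, function(i) {
      x <- simulate_cell_counts(clA, 200, 50, seed = i,
                                sample_id = sprintf("A%02d", i))
      segment_profile(normalize_counts(x), seed = i)
    }),
    lapply(1:5, function(i) {
      x <- simulate_cell_counts(clB, 200, 50, seed = 100 + i,
                                sample_id = sprintf("B%02d", i))
      segment_profile(normalize_counts(x), seed = 100 + i)
    }))
  hm <- cluster_profiles(profs)
  expect_equal(ncol(hm$codes), 10)
  expect_equal(nrow(hm$codes), 200)
  top <- stats::cutree(hm$linkage, k = 2)
  expect_equal(length(unique(top[grepl("^A", names(top))])), 1)
  expect_equal(length(unique(top[grepl("^B", names(top))])), 1)
  expect_false(top[["A01"]] == top[["B01"]])
})

test_that("duplicate profiles merge at height zero; single profile has no tree", {
  g <- make_genome(50, 1, seed = 4)
  p <- structure(list(grid = g,
                      segments = data.frame(chrom = "chr1", start_bin = 0L,
                                            end_bin = 50L, n_bins = 50L,
                                            seg_mean = 1),
                      per_bin = rep(1, 50), sample_id = "p1",
                      analyte = "test"), class = "segmented_profile")
  p2 <- p
  p2$sample_id <- "p2"
  hm <- cluster_profiles(list(p, p2))
  expect_equal(min(hm$linkage$height), 0)
  single <- cluster_profiles(list(p))
  expect_null(single$linkage)
  expect_equal(ncol(single$codes), 1)
})

test_that("heatmap export round-trips codes and places segments on their bins", {
  g <- make_genome(40, 2, seed = 5)
  cl <- simulate_clone(g, data.frame(chrom = "chr1", start_bin = 5,
                                     end_bin = 15, ratio = 1.5))
  p <- liquidbiopsy:::as_segmented_profile(cl)
  p$sample_id <- "cellA"
  flat <- liquidbiopsy:::as_segmented_profile(simulate_clone(g))
  flat$sample_id <- "cellB"
  hm <- cluster_profiles(list(p, flat))
  tsv <- tempfile(fileext = ".tsv")
  pngf <- tempfile(fileext = ".png")
  heatmap_export(hm, tsv, pngf)
  expect_true(file.exists(pngf))
  back <- read_heatmap_tsv(tsv)
  expect_equal(unname(back$codes), unname(hm$codes))
  # the gain occupies exactly its bin rows in the cellA column
  idx <- which(g$chrom == "chr1")[6:15]
  expect_true(all(back$codes[idx, "cellA"] == "gain"))
  expect_true(all(back$codes[-idx, "cellA"] == "neutral"))
  expect_true(all(back$codes[, "cellB"] == "neutral"))
})
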