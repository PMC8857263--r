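# Enumeration, kinetics, SDOM morphometry, variant trajectories.

test_that("analyzed volume is nucleated cells over WBC concentration", {
  expect_equal(volume_analyzed(3e6, 6e6), 0.5)
  expect_equal(volume_analyzed(1, 1), 1)
  expect_equal(volume_analyzed(3e6, 12e6), 0.25)  # doubling halves it
  expect_error(volume_analyzed(0, 6e6), "slide_nucleated_count")
  expect_error(volume_analyzed(3e6, -1), "wbc_per_ml")
})

test_that("enumeration counts cluster members individually and applies positivity", {
  slide <- make_slide(data.frame(
    cell_id = sprintf("c%02d", 1:13),
    class = c(rep("CTC", 10), rep("WBC", 3)),
    stringsAsFactors = FALSE), nucleated = 3e6)
  tp <- enumerate_ctc(slide, wbc_per_ml = 6e6)
  expect_equal(tp$volume_ml, 0.5)
  expect_equal(tp$ctc_per_ml, 20)
  expect_true(tp$positive)
  # a 3-cell cluster appears as 3 rows and contributes 3
  cluster <- make_slide(data.frame(
    cell_id = c("cl.1", "cl.2", "cl.3", "w1"),
    class = c("CTC", "CTC", "CTC", "WBC"),
    cluster_id = c("cl", "cl", "cl", NA),
    stringsAsFactors = FALSE), nucleated = 6e6)
  expect_equal(enumerate_ctc(cluster, wbc_per_ml = 6e6)$n_ctc, 3)
  # 0.76 CTCs/ml is below the >= 1 CTC/ml positivity rule
  sub <- make_slide(data.frame(cell_id = "c1", class = "CTC",
                               stringsAsFactors = FALSE),
                    nucleated = 7.92e6)
  tp2 <- enumerate_ctc(sub, wbc_per_ml = 6e6)   # 1 CTC in 1.32 ml
  expect_equal(tp2$ctc_per_ml, 0.7575, tolerance = 1e-3)
  expect_false(tp2$positive)
  # linearity: doubling CTCs at fixed volume doubles the rate
  expect_equal(enumerate_ctc(slide, 6e6)$ctc_per_ml,
               2 * enumerate_ctc(make_slide(data.frame(
                 cell_id = sprintf("c%02d", 1:8),
                 class = c(rep("CTC", 5), rep("WBC", 3)),
                 stringsAsFactors = FALSE), nucleated = 3e6),
                 6e6)$ctc_per_ml)
})

test_that("kinetics labels follow the 5 CTCs/ml stability rule", {
  expect_equal(classify_kinetics(c(37.08, 52.49))$label, "increasing")
  expect_equal(classify_kinetics(c(10.87, 0.96))$label, "decreasing")
  expect_equal(classify_kinetics(c(1.65, 1.65))$label, "stable")
  expect_equal(classify_kinetics(c(0, 4.99))$label, "stable")
  expect_equal(classify_kinetics(c(0, 5))$label, "increasing")  # boundary
  expect_error(classify_kinetics(37.08), "at least 2")
  # antisymmetry under series reversal
  set.seed(3)
  for (rep in 1:10) {
    v <- runif(6, 0, 60)
    fwd <- classify_kinetics(v)$label
    bwd <- classify_kinetics(rev(v))$label
    swap <- c(increasing = "decreasing", decreasing = "increasing",
              stable = "stable")
    expect_equal(rev(unname(swap[fwd])), bwd)
  }
})

test_that("SDOM is the signed z-score against the nearest-WBC background", {
  # constructed slide: background WBCs with known mean/sd around origin
  set.seed(7)
  wbc <- data.frame(
    cell_id = sprintf("w%03d", 1:60),
    class = "WBC",
    frame_x = runif(60, 0, 100), frame_y = runif(60, 0, 100),
    ck = rnorm(60, 100, 10), stringsAsFactors = FALSE)
  cell <- data.frame(cell_id = "ctc1", class = "CTC",
                     frame_x = 50, frame_y = 50, ck = NA,
                     stringsAsFactors = FALSE)
  slide <- make_slide(rbind(wbc, cell))
  # the background the definition selects: 50 nearest WBCs
  d <- sqrt((wbc$frame_x - 50)^2 + (wbc$frame_y - 50)^2)
  bg <- wbc$ck[order(d, wbc$cell_id)][1:50]
  cell$ck <- mean(bg)
  slide <- make_slide(rbind(wbc, cell))
  expect_equal(as.numeric(sdom(cell, slide, "ck")), 0, tolerance = 1e-12)
  cell$ck <- mean(bg) + 5 * sd(bg)
  slide <- make_slide(rbind(wbc, cell))
  s5 <- sdom(cell, slide, "ck")
  expect_equal(as.numeric(s5), 5, tolerance = 1e-12)
  expect_equal(attr(s5, "n_background"), 50L)
  expect_false(attr(s5, "background_short"))
})

test_that("a 49-WBC slide falls back to all WBCs with a flag", {
  set.seed(8)
  slide49 <- simulate_slide(n_ctc = 2, n_wbc = 49, seed = 8)
  ctc <- slide49[slide49$class == "CTC", ][1, ]
  s <- sdom(ctc, slide49, "ck")
  expect_equal(attr(s, "n_background"), 49L)
  expect_true(attr(s, "background_short"))
  # against a direct nearest-neighbor computation
  wbc <- slide49[slide49$class == "WBC", ]
  bg <- wbc$ck   # all of them
  expect_equal(as.numeric(s), (ctc$ck - mean(bg)) / sd(bg),
               tolerance = 1e-12)
})

test_that("SDOM is invariant under affine rescaling of a channel", {
  slide <- simulate_slide(n_ctc = 5, n_wbc = 80, ctc_intensity_shift = 30,
                          seed = 10)
  ctc <- slide[slide$class == "CTC", ][3, ]
  base <- as.numeric(sdom(ctc, slide, "ck"))
  rescaled <- slide
  rescaled$ck <- 2.5 * slide$ck + 40
  ctc2 <- rescaled[rescaled$class == "CTC", ][3, ]
  expect_equal(as.numeric(sdom(ctc2, rescaled, "ck")), base,
               tolerance = 1e-10)
})

test_that("SDOM rejects degenerate backgrounds and tiny slides", {
  flat <- make_slide(data.frame(
    cell_id = c("c1", sprintf("w%d", 1:5)),
    class = c("CTC", rep("WBC", 5)),
    frame_x = 1:6, frame_y = 1:6, ck = c(9, rep(5, 5)),
    stringsAsFactors = FALSE))
  expect_error(sdom(flat[1, ], flat, "ck"), "degenerate background")
  tiny <- flat[1:2, ]
  expect_error(sdom(tiny[1, ], tiny, "ck"), "at least 2 WBCs")
})

test_that("a shifted CTC population scores its shift in SDOM units", {
  slide <- simulate_slide(n_ctc = 30, n_wbc = 300,
                          ctc_intensity_shift = 50, bg_mean = 100,
                          bg_sd = 10, seed = 12)
  m <- morphometrics(slide, channels = "ck")
  expect_equal(nrow(m), 30)
  # shift = 5 background SDs; the mean SDOM recovers it
  expect_lt(abs(mean(m$sdom_ck) - 5), 0.8)
})

test_that("variant trajectories classify acquired, lost, persistent, transient", {
  draw1 <- data.frame(
    gene = c("ESR1", "ESR1", "PIK3CA", "TP53"),
    protein_change = c("E380Q", "Y537N", "E545K", "R248Q"),
    vaf_percent = c(0.50, 0.33, 2.7, 0.31), stringsAsFactors = FALSE)
  draw2 <- data.frame(
    gene = c("ERBB2", "ESR1", "PIK3CA", "PIK3CA", "TP53", "TP53"),
    protein_change = c("L755S", "E380Q", "E545K", "E726K", "R248Q",
                       "G245D"),
    vaf_percent = c(0.13, 0.07, 30, 0.09, 0.19, 0.11),
    stringsAsFactors = FALSE)
  traj <- track_variants(list(draw1, draw2))
  stat <- setNames(traj$status, paste(traj$gene, traj$protein_change))
  expect_equal(stat[["ERBB2 L755S"]], "acquired")
  expect_equal(stat[["ESR1 Y537N"]], "lost")
  expect_equal(stat[["ESR1 E380Q"]], "persistent")
  expect_equal(stat[["PIK3CA E545K"]], "persistent")
  # the E545K fraction rises 2.7% -> 30%
  e545k <- traj[traj$protein_change == "E545K", ]
  expect_true(e545k$monotone_increase)
})

test_that("a variant present at every analyzed draw with rising VAF is persistent and monotone", {
  tabs <- lapply(c(0.08, 0.47, 2.91, 4.5), function(v) {
    data.frame(gene = "TP53", protein_change = "R213*", vaf_percent = v,
               stringsAsFactors = FALSE)
  })
  traj <- track_variants(tabs, draw_index = c(4, 8, 9, 10))
  expect_equal(traj$status, "persistent")
  expect_true(traj$monotone_increase)
  expect_equal(traj$first_draw, 4)
  expect_equal(traj$last_draw, 10)
  expect_equal(traj$n_draws_present, 4)
})

test_that("trajectory corner cases: single draw, interior-only, row order", {
  single <- track_variants(list(data.frame(gene = "ERBB2",
                                           protein_change = "L755S",
                                           vaf_percent = 14.39)))
  expect_equal(single$status, "persistent")
  # present only at an interior draw: transient
  empty <- data.frame(gene = character(), protein_change = character(),
                      vaf_percent = numeric())
  mid <- data.frame(gene = "TP53", protein_change = "H365fs",
                    vaf_percent = 0.38)
  traj <- track_variants(list(empty, mid, empty))
  expect_equal(traj$status, "transient")
  # NULL draws (no assay) are skipped, not treated as absence
  traj2 <- track_variants(list(mid, NULL, mid))
  expect_equal(traj2$status, "persistent")
  # row order within a draw is irrelevant
  d1 <- data.frame(gene = c("A", "B"), protein_change = c("p1", "p2"),
                   vaf_percent = c(1, 2), stringsAsFactors = FALSE)
  t_fwd <- track_variants(list(d1))
  t_rev <- track_variants(list(d1[2:1, ]))
  key <- function(t) t[order(t$gene), c("gene", "status", "first_vaf")]
  expect_equal(key(t_fwd), key(t_rev), ignore_attr = TRUE)
})
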