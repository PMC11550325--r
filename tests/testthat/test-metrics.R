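test_that("overlap counts match set algebra on constructed masks", {
  a <- mask_at(20, 20, as.matrix(expand.grid(1:10, 1:10)))
  expect_equal(unclass(overlap_counts(a, a))[c("tp", "fp", "fn")],
               list(tp = 100L, fp = 0L, fn = 0L))
  b <- mask_at(20, 20, as.matrix(expand.grid(11:20, 11:20)))
  expect_equal(unclass(overlap_counts(a, b))[c("tp", "fp", "fn")],
               list(tp = 0L, fp = 100L, fn = 100L))
  # 10x10 squares at x-offset 5: analytic rectangle overlap
  c5 <- mask_at(20, 20, as.matrix(expand.grid(1:10, 6:15)))
  expect_equal(unclass(overlap_counts(a, c5))[c("tp", "fp", "fn")],
               list(tp = 50L, fp = 50L, fn = 50L))
  expect_error(overlap_counts(a, mask_at(5, 5, cbind(1, 1))), "mismatch")
})

test_that("dice handles the worked examples and empty conventions", {
  oc <- function(tp, fp, fn) structure(list(tp = tp, fp = fp, fn = fn),
                                       class = "overlap_counts")
  expect_equal(dice(oc(100, 0, 0)), 1.0)
  expect_equal(dice(oc(50, 50, 50)), 0.5)
  expect_equal(dice(oc(0, 0, 0)), 1.0)   # both empty
  expect_equal(dice(oc(0, 10, 0)), 0.0)  # one empty
})

test_that("error fractions use the union denominator", {
  oc <- function(tp, fp, fn) structure(list(tp = tp, fp = fp, fn = fn),
                                       class = "overlap_counts")
  expect_equal(error_fractions(oc(100, 0, 0)),
               c(fp_frac = 0, fn_frac = 0))
  expect_equal(error_fractions(oc(50, 50, 50)),
               c(fp_frac = 1 / 3, fn_frac = 1 / 3))
  expect_error(error_fractions(oc(0, 0, 0)), "undefined")
})

test_that("dice identity holds on random masks and dice is symmetric", {
  set.seed(31)
  for (k in 1:200) {
    a <- binary_mask(matrix(runif(144) < 0.4, 12, 12))
    b <- binary_mask(matrix(runif(144) < 0.4, 12, 12))
    cts <- overlap_counts(a, b)
    if (cts$tp + cts$fp + cts$fn == 0) next
    fr <- error_fractions(cts)
    s <- fr[["fp_frac"]] + fr[["fn_frac"]]
    expect_equal(dice(cts), 2 * (1 - s) / (2 - s), tolerance = 1e-12)
    expect_identical(dice(cts), dice(overlap_counts(b, a)))
    expect_gte(dice(cts), 0); expect_lte(dice(cts), 1)
  }
})

test_that("growing the prediction outside gt increases fp, never fn", {
  set.seed(32)
  gt <- binary_mask(matrix(runif(100) < 0.3, 10, 10))
  p <- binary_mask(matrix(runif(100) < 0.3, 10, 10))
  for (k in 1:20) {
    outside <- which(!p & !gt)
    if (!length(outside)) break
    p2 <- unclass(p); p2[sample(outside, 1)] <- TRUE
    p2 <- binary_mask(p2)
    c1 <- overlap_counts(gt, p); c2 <- overlap_counts(gt, p2)
    expect_equal(c2$fp, c1$fp + 1L)
    expect_identical(c2$fn, c1$fn)
    p <- p2
  }
})

test_that("mask centroid matches brute-force pixel means", {
  full <- binary_mask(matrix(TRUE, 10, 10))
  expect_equal(mask_centroid(full), c(row = 5, col = 5))
  one <- mask_at(10, 10, cbind(4, 8))  # 0-based (r=3, c=7)
  expect_equal(mask_centroid(one), c(row = 3.5, col = 7.5))
  # L-shape: brute-force mean over an explicit pixel list
  cells <- rbind(as.matrix(expand.grid(1:10, 1:2)),
                 as.matrix(expand.grid(9:10, 3:10)))
  L <- mask_at(12, 12, cells)
  expect_equal(mask_centroid(L),
               c(row = mean(cells[, 1] - 0.5), col = mean(cells[, 2] - 0.5)))
  expect_error(mask_centroid(binary_mask(matrix(FALSE, 3, 3))), "empty")
})

test_that("centroid containment, including the annulus counterexample", {
  gt <- mask_at(20, 20, as.matrix(expand.grid(5:15, 5:15)))
  expect_true(centroid_contained(gt, gt))
  patch <- mask_at(20, 20, as.matrix(expand.grid(10:11, 10:11)))
  expect_true(centroid_contained(gt, patch))
  # annulus: centroid pixel falls in the hole
  ring_cells <- as.matrix(expand.grid(5:15, 5:15))
  inner <- ring_cells[, 1] >= 7 & ring_cells[, 1] <= 13 &
           ring_cells[, 2] >= 7 & ring_cells[, 2] <= 13
  ann <- mask_at(20, 20, ring_cells[!inner, ])
  ctr <- mask_centroid(ann)
  expect_false(ann[floor(ctr[["row"]]) + 1, floor(ctr[["col"]]) + 1])
  expect_false(centroid_contained(ann, ann))
  expect_error(centroid_contained(binary_mask(matrix(FALSE, 3, 3)),
                                  binary_mask(matrix(FALSE, 3, 3))), "empty")
})

test_that("evaluate_annotation combines the metrics coherently", {
  gt <- mask_at(20, 20, as.matrix(expand.grid(3:12, 3:12)))
  rec <- evaluate_annotation(gt, gt, "a", "i", "PRE")
  expect_equal(rec$dice, 1); expect_equal(rec$fp_frac, 0)
  expect_equal(rec$fn_frac, 0); expect_true(rec$centroid_hit)

  half <- mask_at(20, 20, as.matrix(expand.grid(3:12, 8:17)))
  rec2 <- evaluate_annotation(gt, half, "a", "i", "POST")
  expect_equal(rec2$dice, 0.5)
  expect_equal(rec2$fp_frac, 1 / 3); expect_equal(rec2$fn_frac, 1 / 3)

  none <- binary_mask(matrix(FALSE, 20, 20))
  rec3 <- evaluate_annotation(gt, none, "a", "i", "POST")
  expect_equal(rec3$dice, 0)
  expect_equal(rec3$fp_frac, 0); expect_equal(rec3$fn_frac, 1)
  expect_false(rec3$centroid_hit)
})

test_that("classify_change detects pixel changes and dice ties", {
  gt <- mask_at(20, 20, as.matrix(expand.grid(5:14, 5:14)))
  left <- mask_at(20, 20, as.matrix(expand.grid(5:14, 4:13)))
  right <- mask_at(20, 20, as.matrix(expand.grid(5:14, 6:15)))
  r_gt <- function(m, rd) evaluate_annotation(gt, m, "a", "i", rd)

  same <- classify_change(left, left, r_gt(left, "PRE"), r_gt(left, "POST"))
  expect_false(same$annotation_changed)
  expect_equal(same$dice_outcome, "UNCHANGED")

  up <- classify_change(left, gt, r_gt(left, "PRE"), r_gt(gt, "POST"))
  expect_true(up$annotation_changed)
  expect_equal(up$dice_outcome, "IMPROVED")

  # mirrored offsets: distinct masks, identical dice
  tie <- classify_change(left, right, r_gt(left, "PRE"), r_gt(right, "POST"))
  expect_true(tie$annotation_changed)
  expect_equal(tie$dice_outcome, "UNCHANGED")

  expect_error(classify_change(left, right, r_gt(left, "PRE"),
                               evaluate_annotation(gt, right, "b", "i", "POST")),
               "different annotator")
})

test_that("rectangle-pair overlap counts equal closed-form areas", {
  f <- image_frame("i", 30, 30)
  set.seed(33)
  for (k in 1:40) {
    g <- sort(sample(0:29, 2)); gy <- sort(sample(0:29, 2))
    p <- sort(sample(0:29, 2)); py <- sort(sample(0:29, 2))
    if (diff(g) == 0 || diff(gy) == 0 || diff(p) == 0 || diff(py) == 0) next
    gm <- rasterize(polygon_annotation("g", "i", "GROUND_TRUTH",
                                       square_ring(g[1], gy[1], g[2], gy[2])), f)
    pm <- rasterize(polygon_annotation("p", "i", "PRE",
                                       square_ring(p[1], py[1], p[2], py[2])), f)
    inter <- max(0, min(g[2], p[2]) - max(g[1], p[1])) *
             max(0, min(gy[2], py[2]) - max(gy[1], py[1]))
    area_g <- diff(g) * diff(gy); area_p <- diff(p) * diff(py)
    cts <- overlap_counts(gm, pm)
    expect_identical(cts$tp, as.integer(inter))
    expect_identical(cts$fp, as.integer(area_p - inter))
    expect_identical(cts$fn, as.integer(area_g - inter))
  }
})
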