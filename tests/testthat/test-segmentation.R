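# Instance matching, F1 at IoU, crop extraction, reference segmenter.

make_mask <- function(rects, dim = c(40, 40)) {
  m <- matrix(0L, dim[1], dim[2])
  for (i in seq_along(rects)) {
    r <- rects[[i]]
    m[r[1]:r[2], r[3]:r[4]] <- i
  }
  instance_mask(m)
}

test_that("identical and empty masks give the expected counts", {
  gt <- make_mask(list(c(2, 6, 2, 6), c(10, 15, 10, 15), c(25, 30, 5, 9)))
  m <- match_instances(gt, gt, 0.5)
  expect_equal(c(m$TP, m$FP, m$FN), c(3, 0, 0))
  expect_equal(f1_at_iou(m), 1)
  empty <- instance_mask(matrix(0L, 40, 40))
  m2 <- match_instances(make_mask(list(c(1, 5, 1, 5), c(8, 12, 8, 12),
                                       c(20, 24, 20, 24), c(30, 34, 30, 34))),
                        empty, 0.5)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(0, 0, 4))
  expect_equal(f1_at_iou(m2), 0)
  # empty-vs-empty scene is defined as perfect agreement
  expect_equal(f1_at_iou(match_instances(empty, empty, 0.5)), 1)
})

test_that("the shifted square crosses the IoU threshold as computed by hand", {
  # 10x10 square shifted by 5 columns: overlap 50 px, union 150 px, IoU 1/3
  gt <- matrix(0L, 30, 30); gt[10:19, 5:14] <- 1L
  pr <- matrix(0L, 30, 30); pr[10:19, 10:19] <- 1L
  gt <- instance_mask(gt); pr <- instance_mask(pr)
  m03 <- match_instances(gt, pr, 0.3)
  expect_equal(m03$TP, 1)
  expect_equal(m03$matches$iou, 1 / 3, tolerance = 1e-12)
  m05 <- match_instances(gt, pr, 0.5)
  expect_equal(c(m05$TP, m05$FP, m05$FN), c(0, 1, 1))
  curve <- f1_curve(gt, pr, c(0.3, 0.5))
  expect_equal(curve$F1, c(1, 0))
})

test_that("direct substitution into the F1 formula holds", {
  m <- structure(list(TP = 3, FP = 1, FN = 2), class = "match_result")
  expect_equal(f1_at_iou(m), 6 / 9)
  expect_equal(f1_at_iou(structure(list(TP = 0, FP = 2, FN = 3),
                                   class = "match_result")), 0)
})

test_that("matching agrees with the exhaustive bipartite oracle", {
  for (s in 1:30) {
    sc <- random_scene(s)
    for (thr in c(0.3, 0.5, 0.75)) {
      m <- match_instances(sc$gt, sc$pred, thr)
      o <- oracle_match_counts(sc$gt, sc$pred, thr)
      expect_equal(m$TP, o$TP, info = sprintf("seed %d thr %.2f", s, thr))
      expect_equal(m$FP, o$FP)
      expect_equal(m$FN, o$FN)
      expect_true(all(m$matches$iou >= thr))
      expect_false(anyDuplicated(m$matches$gt) > 0)
      expect_false(anyDuplicated(m$matches$pred) > 0)
    }
  }
})

test_that("f1_curve is non-increasing in threshold", {
  for (s in 31:45) {
    sc <- random_scene(s)
    curve <- f1_curve(sc$gt, sc$pred, seq(0.2, 0.9, by = 0.1))
    expect_true(all(diff(curve$F1) <= 1e-12))
  }
  expect_error(f1_curve(random_scene(1)$gt, random_scene(1)$pred, c(0.5, 0.5)),
               "increasing")
})

test_that("shape mismatch and bad thresholds are rejected", {
  a <- instance_mask(matrix(0L, 10, 10))
  b <- instance_mask(matrix(0L, 12, 10))
  expect_error(match_instances(a, b, 0.5), "shape")
  expect_error(match_instances(a, a, 0), "iou_threshold")
  expect_error(match_instances(a, a, 1), "iou_threshold")
})

test_that("crop extraction centers, pads and isolates the target cell", {
  set.seed(11)
  frame_arr <- array(round(runif(90 * 90 * 4, 0, 60000)), c(90, 90, 4))
  frame <- if_frame(frame_arr)
  mask <- matrix(0L, 90, 90)
  mask[40:51, 40:49] <- 1L           # area 120, interior
  mask[40:51, 50:55] <- 2L           # adjacent neighbour
  mask[8:12, 8:12] <- 3L             # near the corner -> padding
  mask <- instance_mask(mask)
  cr <- extract_crop(frame, mask, 1L)
  expect_equal(sum(cr[, , 5]), 120)
  expect_equal(dim(cr), c(75L, 75L, 5L))
  # centre pixel lies inside the cell's mask
  expect_equal(unname(cr[38, 38, 5]), 1)
  # channel 5 is the indicator of the target cell only: reconstructing the
  # crop window around the centroid must match exactly, so the adjacent
  # neighbour's pixels are zero even though they fall inside the window
  ctr_r <- floor(mean(which(mask == 1L, arr.ind = TRUE)[, 1]) + 0.5)
  ctr_c <- floor(mean(which(mask == 1L, arr.ind = TRUE)[, 2]) + 0.5)
  win <- mask[(ctr_r - 37):(ctr_r + 37), (ctr_c - 37):(ctr_c + 37)]
  expect_equal(unname(cr[, , 5]), (unclass(win) == 1L) + 0)
  expect_gt(sum(win == 2L), 0)      # the neighbour really is in the window
  # neighbour's own crop carries its full mask
  cr2 <- extract_crop(frame, mask, 2L)
  expect_equal(sum(cr2[, , 5]), sum(mask == 2L))
  crc <- extract_crop(frame, mask, 3L)
  expect_equal(dim(crc), c(75L, 75L, 5L))
  expect_equal(sum(crc[, , 5]), 25)
  # zero padding beyond the frame edge
  expect_true(all(crc[1:20, 1:20, 1] == 0))
  expect_error(extract_crop(frame, mask, 99L), "99")
})

test_that("crop extraction is translation-consistent for interior cells", {
  set.seed(12)
  arr <- array(round(runif(100 * 100 * 4, 0, 65535)), c(100, 100, 4))
  mask <- matrix(0L, 100, 100)
  mask[45:56, 48:57] <- 1L
  dr <- 4; dc <- 7
  arr2 <- array(0, dim(arr))
  arr2[(1 + dr):100, (1 + dc):100, ] <- arr[1:(100 - dr), 1:(100 - dc), ]
  mask2 <- matrix(0L, 100, 100)
  mask2[(1 + dr):100, (1 + dc):100] <- mask[1:(100 - dr), 1:(100 - dc)]
  c1 <- extract_crop(if_frame(arr), instance_mask(mask), 1L)
  c2 <- extract_crop(if_frame(arr2), instance_mask(mask2), 1L)
  expect_equal(unclass(c1), unclass(c2))
})

test_that("the reference segmenter recovers well-separated nuclei", {
  cfg <- slide_config(frame_nrow = 300, frame_ncol = 300, n_frames = 1,
                      n_cells = 5,
                      rare_fractions = setNames(rep(0, 7), rare_phenotypes()),
                      blur_sigma_range = c(0, 0), artifacts = FALSE, seed = 21)
  s <- generate_slide(cfg)
  pred <- reference_segment(s$frames[[1]])
  expect_equal(length(setdiff(unique(as.vector(pred)), 0)), 5)
  m <- match_instances(s$masks[[1]], pred, 0.5)
  expect_equal(f1_at_iou(m), 1)
  # determinism
  expect_identical(unclass(pred), unclass(reference_segment(s$frames[[1]])))
  # blank frame -> empty mask, no error
  blank <- if_frame(array(0, c(50, 50, 4)))
  expect_equal(sum(reference_segment(blank)), 0)
})
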