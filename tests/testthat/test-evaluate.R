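test_that("matching recovers identical sets perfectly", {
  gt <- centroid_set(x = c(10, 30, 50), y = c(10, 10, 10), z = c(5, 5, 5))
  m <- match_centroids(gt, gt)
  expect_equal(nrow(m$pairs), 3)
  expect_equal(m$pairs$distance, rep(0, 3))
  expect_length(m$unmatched_gt, 0)
  expect_length(m$unmatched_est, 0)
})

test_that("the matching window is a closed ball of the stated radius", {
  gt <- centroid_set(x = 10, y = 10, z = 10)
  far <- centroid_set(x = 21, y = 10, z = 10)     # distance 11
  m <- match_centroids(gt, far, radius = 10)
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$unmatched_gt, 1L)
  expect_equal(m$unmatched_est, 1L)
  edge <- centroid_set(x = 20, y = 10, z = 10)    # distance exactly 10
  expect_equal(nrow(match_centroids(gt, edge, radius = 10)$pairs), 1)
})

test_that("the closest estimate in a window wins; the other counts FP", {
  gt <- centroid_set(x = 10, y = 10, z = 10)
  est <- centroid_set(x = c(14, 17), y = c(10, 10), z = c(10, 10),
                      label = c(7L, 8L))
  m <- match_centroids(gt, est, radius = 10)
  expect_equal(m$pairs$est_label, 7L)
  expect_equal(m$pairs$distance, 4)
  expect_equal(m$unmatched_est, 8L)
  met <- detection_metrics(m, gt, est)
  expect_equal(met$tp, 1); expect_equal(met$fp, 1); expect_equal(met$fn, 0)
})

test_that("matching is invariant to input order and relabelling", {
  pts_g <- withr::with_seed(51, matrix(runif(24, 0, 40), 8, 3))
  pts_e <- pts_g + withr::with_seed(52, matrix(rnorm(24, 0, 3), 8, 3))
  gt <- centroid_set(pts_g[, 1], pts_g[, 2], pts_g[, 3])
  est <- centroid_set(pts_e[, 1], pts_e[, 2], pts_e[, 3])
  m1 <- match_centroids(gt, est)
  perm <- withr::with_seed(53, sample(8))
  est2 <- est[perm, ]
  est2$label <- 101:108   # relabel + reorder
  m2 <- match_centroids(gt, est2)
  expect_equal(nrow(m1$pairs), nrow(m2$pairs))
  expect_equal(sort(m1$pairs$distance), sort(m2$pairs$distance))
  expect_equal(sort(m1$pairs$gt_label), sort(m2$pairs$gt_label))
})

test_that("metrics reproduce hand-computed values and identities", {
  gt <- centroid_set(x = c(0, 20, 40, 60), y = rep(0, 4), z = rep(0, 4))
  est <- centroid_set(x = c(3, 24, 100), y = rep(0, 3), z = rep(0, 3))
  m <- match_centroids(gt, est, radius = 10)
  met <- detection_metrics(m, gt, est, volume_shape = c(100, 50, 20))
  expect_equal(met$tp, 2)
  expect_equal(met$fp, 1)
  expect_equal(met$fn, 2)
  expect_equal(met$sensitivity, 100 * 2 / 4)
  expect_equal(met$precision, 100 * 2 / 3)
  expect_equal(met$rmse, sqrt((3^2 + 4^2) / 2))
  tn <- 100 * 50 * 20 - 4 - 1
  expect_equal(met$specificity, 100 * tn / (tn + 1))
  # identities TP + FN = N_GT, TP + FP = N_est on random sets
  for (seed in 1:3) {
    pg <- withr::with_seed(seed, matrix(runif(15, 0, 30), 5, 3))
    pe <- withr::with_seed(seed + 10, matrix(runif(21, 0, 30), 7, 3))
    g <- centroid_set(pg[, 1], pg[, 2], pg[, 3])
    e <- centroid_set(pe[, 1], pe[, 2], pe[, 3])
    mm <- detection_metrics(match_centroids(g, e), g, e)
    expect_equal(mm$tp + mm$fn, 5)
    expect_equal(mm$tp + mm$fp, 7)
    expect_gte(mm$sensitivity, 0); expect_lte(mm$sensitivity, 100)
    expect_gte(mm$precision, 0); expect_lte(mm$precision, 100)
  }
})

test_that("degenerate metric inputs are handled explicitly", {
  gt <- centroid_set(x = 5, y = 5, z = 5)
  expect_error(detection_metrics(match_centroids(gt, gt), centroid_set(), gt),
               class = "nuclei3d_validation_error")
  empty <- centroid_set()
  m <- match_centroids(gt, empty)
  expect_warning(met <- detection_metrics(m, gt, empty), "precision")
  expect_equal(met$precision, 0)
  expect_true(is.na(met$rmse))
})

test_that("specificity is dominated by true negatives at volume scale", {
  # <= 33 centroids and modest FP in a 261 x 261 x 224 volume force > 99%
  gt <- centroid_set(x = seq(20, 180, 5), y = rep(100, 33), z = rep(100, 33))
  est <- centroid_set(x = c(seq(20, 180, 5) + 1, 240, 250),
                      y = rep(100, 35), z = rep(100, 35))
  m <- match_centroids(gt, est)
  met <- detection_metrics(m, gt, est, volume_shape = c(261, 261, 224))
  expect_gt(met$specificity, 99)
})

test_that("standard error matches the closed form and the sd oracle", {
  expect_equal(standard_error(rep(7, 5)), 0)
  expect_equal(standard_error(c(0, 2)), 1)
  x <- withr::with_seed(54, rnorm(17))
  expect_equal(standard_error(x),
               sqrt(sum((x - mean(x))^2) / (17 * 16)))
  expect_error(standard_error(3), class = "nuclei3d_validation_error")
})
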