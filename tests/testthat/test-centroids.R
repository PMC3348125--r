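test_that("characteristic ratio is 1 at unique maxima and on plateaus", {
  a <- rand_volume(c(7, 7, 7), seed = 31, lo = 1, hi = 50)
  a[4, 4, 4] <- 100  # strict unique maximum of the full neighbourhood
  expect_equal(characteristic_ratio(a, c(4, 4, 4), 7), 1)
  flat <- array(3, c(7, 7, 7))
  expect_equal(characteristic_ratio(flat, c(4, 4, 4), 7), 1)  # ties count
  expect_error(characteristic_ratio(a, c(0, 4, 4)),
               class = "nuclei3d_validation_error")
})

test_that("characteristic ratio matches the nested-loop count everywhere", {
  a <- withr::with_seed(30, array(sample.int(40, 7^3, replace = TRUE), c(7, 7, 7)))
  for (vox in list(c(4, 4, 4), c(1, 1, 1), c(7, 4, 2), c(2, 6, 7))) {
    expect_equal(characteristic_ratio(a, vox, 7), oracle_ratio(a, vox, 7))
    expect_equal(characteristic_ratio(a, vox, 3), oracle_ratio(a, vox, 3))
  }
})

test_that("the ratio map agrees with per-voxel ratios and masks zeros", {
  a <- rand_volume(c(6, 5, 4), seed = 32, lo = 1, hi = 9)
  a[2, 2, 2] <- 0
  r <- ratio_image(a, 3)
  expect_true(is.na(r[2, 2, 2]))
  for (i in c(1, 3, 6)) for (j in c(1, 5)) for (k in c(1, 4))
    expect_equal(r[i, j, k], oracle_ratio(a, c(i, j, k), 3))
})

test_that("the ratio is invariant under strictly monotone transforms", {
  a <- rand_volume(c(9, 9, 9), seed = 33, lo = 1, hi = 10)
  r1 <- ratio_image(a, 5)
  r2 <- ratio_image(a^3, 5)           # strictly increasing transform
  r3 <- ratio_image(exp(a / 4), 5)
  expect_equal(r1, r2)
  expect_equal(r1, r3)
})

test_that("stage 1 finds one candidate per well-separated ball", {
  a <- make_ball(c(41, 41, 41), c(21, 21, 21), 12, background = 5)
  lei <- local_enhance(nuc_volume(a, c(1, 1, 1)), scale_lengths(24))
  s1 <- stage1_candidates(lei)
  expect_equal(nrow(s1), 1)
  expect_lt(sqrt(sum((c(s1$x, s1$y, s1$z) - 21)^2)), 1)

  b <- make_ball(c(70, 36, 36), c(18, 18, 18), 10, background = 5) +
    make_ball(c(70, 36, 36), c(52, 18, 18), 12, background = 0)
  lei2 <- local_enhance(nuc_volume(b, c(1, 1, 1)), scale_lengths(24))
  s1b <- stage1_candidates(lei2)
  expect_equal(nrow(s1b), 2)
  d_to <- function(df, p) sqrt((df$x - p[1])^2 + (df$y - p[2])^2 +
                                 (df$z - p[3])^2)
  expect_lt(min(d_to(s1b, c(18, 18, 18))), 1)
  expect_lt(min(d_to(s1b, c(52, 18, 18))), 1)

  zero <- nuc_volume(array(0, c(10, 10, 10)), c(1, 1, 1))
  expect_warning(s0 <- stage1_candidates(zero), "no candidate")
  expect_equal(nrow(s0), 0)
})

test_that("slope labels mark rises, falls and plateaus", {
  expect_equal(slope_labels(c(1, 2, 3, 2, 1)), c(1L, 1L, -1L, -1L))
  expect_equal(slope_labels(rep(4, 6)), rep(0L, 5))
  p <- withr::with_seed(34, runif(15))
  expect_equal(slope_labels(p),
               vapply(seq_len(14), function(i) {
                 if (p[i + 1] > p[i]) 1L else if (p[i + 1] < p[i]) -1L else 0L
               }, integer(1)))
})

test_that("shape score rewards symmetric convexity only", {
  expect_equal(shape_score(c(0, 1, 2, 3, 2, 1, 0)), 1)
  expect_equal(shape_score(rep(5, 7)), 0)                  # flat
  expect_equal(shape_score(seq(0, 6)), 0)                  # linear
  expect_equal(shape_score(c(0, 1, 2, 3, 3, 1, 0)), 2 / 3) # one flat slope
  expect_error(shape_score(c(1, 2, 3, 4)), class = "nuclei3d_validation_error")
  # in [0, 1]; 1 only for all-up left and all-down right
  for (seed in 1:20) {
    p <- withr::with_seed(seed, runif(9))
    s <- shape_score(p)
    expect_gte(s, 0); expect_lte(s, 1)
    lab <- slope_labels(p)
    if (s == 1) {
      expect_true(all(lab[1:4] == 1L) && all(lab[5:8] == -1L))
    }
  }
  # clipped profiles scored against the nominal length are penalized
  expect_equal(shape_score(c(0, 1, 0), nominal_length = 21), 2 / 20)
})

test_that("stage 2 keeps convex-profile candidates and drops background", {
  a <- make_ball(c(41, 41, 41), c(21, 21, 21), 12, background = 5)
  lei <- local_enhance(nuc_volume(a, c(1, 1, 1)), scale_lengths(24))
  cands <- centroid_set(x = c(21, 6), y = c(21, 35), z = c(21, 35))
  kept <- stage2_refine(lei, cands, dmax = 24)
  expect_equal(kept$label, 1L)        # ideal ball retained ...
  expect_equal(kept$score, 1)         # ... with the maximum score
})

test_that("stage 2 survivors equal the per-candidate profile oracle", {
  out <- generate_embryo(small_spec(seed = 35))
  lei <- local_enhance(smooth_volume(out$volume), scale_lengths(30))
  s1 <- stage1_candidates(lei)
  s2 <- stage2_refine(lei, s1, dmax = 30)
  # oracle: recompute every final score with direct array slicing
  a <- lei$data; d <- dim(a)
  np <- 21L; half <- 10L
  oracle_scores <- vapply(seq_len(nrow(s1)), function(i) {
    cen <- pmin(pmax(round(c(s1$x[i], s1$y[i], s1$z[i])), 1), d)
    ax_score <- function(ax) {
      h <- min(half, cen[ax] - 1, d[ax] - cen[ax])
      if (h < 1) return(0)
      idx <- lapply(1:3, function(t) if (t == ax) (cen[t] - h):(cen[t] + h)
                    else cen[t])
      shape_score(as.vector(a[idx[[1]], idx[[2]], idx[[3]]]),
                  nominal_length = np)
    }
    mean(c(ax_score(1), ax_score(2), ax_score(3)))
  }, numeric(1))
  expect_equal(s2$label, s1$label[oracle_scores >= 0.85])
  expect_equal(s2$score, oracle_scores[oracle_scores >= 0.85])
})

test_that("pairwise distances are Euclidean, symmetric and zero-diagonal", {
  cs <- centroid_set(x = c(0, 3), y = c(0, 4), z = c(0, 0))
  m <- pairwise_distances(cs)
  expect_equal(m[1, 2], 5)
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(c(0, 0), 1:2))
  expect_equal(dim(pairwise_distances(centroid_set(1, 1, 1))), c(1, 1))
  pts <- withr::with_seed(36, matrix(runif(30, 0, 50), 10, 3))
  cs2 <- centroid_set(pts[, 1], pts[, 2], pts[, 3])
  m2 <- pairwise_distances(cs2)
  for (i in 1:10) for (j in 1:10)
    expect_equal(m2[i, j], sqrt(sum((pts[i, ] - pts[j, ])^2)))
})

test_that("stage 3 merges by transitive closure and averages coordinates", {
  # all pairs farther than T_D: unchanged apart from relabelling
  cs <- centroid_set(x = c(0, 40, 80), y = c(0, 0, 0), z = c(0, 0, 0))
  m1 <- stage3_merge(cs, 15)
  expect_equal(nrow(m1), 3)
  expect_equal(m1$label, 1:3)

  # two fragments 8 apart merge at their midpoint
  cs2 <- centroid_set(x = c(10, 18), y = c(5, 5), z = c(7, 7))
  m2 <- stage3_merge(cs2, 15)
  expect_equal(nrow(m2), 1)
  expect_equal(c(m2$x, m2$y, m2$z), c(14, 5, 7))

  # chain A-B-C with d(A,B) = d(B,C) = 10, d(A,C) = 20: one group of three
  cs3 <- centroid_set(x = c(0, 10, 20), y = c(0, 0, 0), z = c(0, 0, 0))
  m3 <- stage3_merge(cs3, 15)
  expect_equal(nrow(m3), 1)
  expect_equal(m3$x, 10)
  expect_equal(m3$n_members, 3L)
})

test_that("stage 3 grouping equals the brute-force closure on random sets", {
  for (seed in 1:5) {
    pts <- withr::with_seed(seed, matrix(runif(36, 0, 60), 12, 3))
    cs <- centroid_set(pts[, 1], pts[, 2], pts[, 3])
    td <- 12
    merged <- stage3_merge(cs, td)
    grp <- oracle_closure_groups(pts, td)
    expect_equal(nrow(merged), max(grp))
    expect_equal(sum(merged$n_members), 12L)   # a partition
    want <- t(vapply(seq_len(max(grp)), function(g)
      colMeans(pts[grp == g, , drop = FALSE]), numeric(3)))
    got <- as.matrix(merged[, c("x", "y", "z")])
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 unname(want[order(want[, 1], want[, 2]), , drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("stage 3 is idempotent on fragment clusters", {
  # fragments scattered around well-separated true centres
  centres <- rbind(c(20, 20, 20), c(70, 20, 20), c(45, 70, 45))
  pts <- do.call(rbind, lapply(seq_len(3), function(i)
    sweep(withr::with_seed(40 + i, matrix(runif(9, -4, 4), 3, 3)), 2,
          centres[i, ], "+")))
  cs <- centroid_set(pts[, 1], pts[, 2], pts[, 3])
  once <- stage3_merge(cs, 15)
  twice <- stage3_merge(once, 15)
  expect_equal(nrow(once), 3)
  expect_equal(twice[, c("x", "y", "z")], once[, c("x", "y", "z")])
})
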