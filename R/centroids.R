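#' Characteristic ratio at one voxel
#'
#' The fraction of voxels in the cubic neighbourhood (centre included) whose
#' intensity is less than or equal to the centre intensity, counted over the
#' in-bounds part of the neighbourhood only.  The ratio is 1 exactly when
#' the centre is a (weak) maximum of its neighbourhood: a strict unique peak
#' gives 1, and so does a constant neighbourhood because ties count.
#'
#' @param v A [nuc_volume()] or 3D array.
#' @param voxel Integer (x, y, z) position, 1-based.
#' @param neighborhood Odd cube edge in voxels (default 7).
#' @return The ratio in (0, 1].
#' @export
characteristic_ratio <- function(v, voxel, neighborhood = 7L) {
  a <- vol_data(v)
  d <- dim(a)
  voxel <- as.integer(voxel)
  neighborhood <- as.integer(neighborhood)
  if (neighborhood < 3L || neighborhood %% 2L == 0L)
    stop_validation("`neighborhood` must be an odd integer >= 3")
  if (length(voxel) != 3L || any(voxel < 1L) || any(voxel > d))
    stop_validation("`voxel` out of volume bounds")
  h <- (neighborhood - 1L) %/% 2L
  lo <- pmax(voxel - h, 1L)
  hi <- pmin(voxel + h, d)
  block <- a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  centre <- a[voxel[1], voxel[2], voxel[3]]
  sum(block <= centre) / length(block)
}

#' Characteristic-ratio map of a volume
#'
#' Computes the characteristic ratio at every voxel with intensity > 0
#' (`NA` elsewhere), with neighbourhoods clipped at the volume boundary.
#'
#' @inheritParams characteristic_ratio
#' @return A 3D array of ratios in (0, 1] with `NA` on non-positive voxels.
#' @export
ratio_image <- function(v, neighborhood = 7L) {
  a <- vol_data(v)
  neighborhood <- as.integer(neighborhood)
  if (neighborhood < 3L || neighborhood %% 2L == 0L)
    stop_validation("`neighborhood` must be an odd integer >= 3")
  r <- ratio_map_cpp(as.vector(a), dim(a), (neighborhood - 1L) %/% 2L)
  array(r, dim(a))
}

#' Stage 1: candidate centroids from characteristic-ratio clusters
#'
#' Builds the binary cluster image `M(x) = 1` iff `LEI(x) > 0` and the
#' characteristic ratio at `x` reaches `ratio_threshold`, labels it with
#' 26-connectivity, and places one candidate at the unweighted mean of each
#' component's voxel coordinates.  With a hybrid-image LEI (zero outside the
#' candidate regions) only candidate-region voxels are ever evaluated.
#'
#' @param lei The locally enhanced image, a [nuc_volume()].
#' @param neighborhood Odd cube edge of the ratio neighbourhood (default 7).
#' @param ratio_threshold Minimum characteristic ratio T_R (default 0.97).
#' @return A centroid tibble with columns `label`, `x`, `y`, `z`, `score`
#'   (`NA` at this stage) and `n_voxels` (cluster size).  Empty, with a
#'   warning, when no cluster passes.
#' @export
stage1_candidates <- function(lei, neighborhood = 7L, ratio_threshold = 0.97) {
  if (ratio_threshold <= 0 || ratio_threshold > 1)
    stop_validation("`ratio_threshold` must lie in (0, 1]")
  a <- vol_data(lei)
  d <- dim(a)
  r <- ratio_image(a, neighborhood)
  m <- !is.na(r) & r >= ratio_threshold
  if (!any(m)) {
    warn("no candidate centroids found")
    out <- centroid_set()
    out$n_voxels <- integer()
    return(out)
  }
  lab <- label3d_cpp(as.integer(m), d)
  idx <- which(lab > 0L)
  lv <- lab[idx]
  co <- arrayInd(idx, d)
  n <- tabulate(lv)
  out <- centroid_set(
    x = rowsum(co[, 1], lv)[, 1] / n,
    y = rowsum(co[, 2], lv)[, 1] / n,
    z = rowsum(co[, 3], lv)[, 1] / n,
    label = seq_along(n))
  out$n_voxels <- n
  out
}

#' Slope labels of an intensity profile
#'
#' For each adjacent pair of samples, +1 if the profile rises, -1 if it
#' falls, 0 if it is flat.
#'
#' @param p Numeric profile of length >= 2.
#' @return Integer vector of length `length(p) - 1`.
#' @export
slope_labels <- function(p) {
  if (length(p) < 2)
    stop_validation("profile needs at least 2 samples")
  as.integer(sign(diff(p)))
}

#' Shape score of a centred intensity profile
#'
#' Measures how symmetrically convex a profile is around its centre without
#' curve fitting: with `m = (N - 1) / 2` slopes on each side of the centre,
#' `S = 2 * min(n_up_left, n_down_right) / (N - 1)`, where `n_up_left`
#' counts +1 slopes left of the centre and `n_down_right` counts -1 slopes
#' right of it.  S is 1 only for profiles rising on every left step and
#' falling on every right step; flat or monotone (linear) profiles score 0.
#'
#' @param p Numeric profile of odd length >= 3, centred on the candidate.
#' @param nominal_length Length whose slope count normalizes the score
#'   (default: the profile's own length).  When a border-clipped profile is
#'   scored against the full nominal length, the unobservable slopes count
#'   as non-supporting, so partial boundary objects cannot reach high
#'   scores on the strength of two or three samples.
#' @return The score in `[0, 1]`.
#' @export
shape_score <- function(p, nominal_length = length(p)) {
  n <- length(p)
  if (n < 3 || n %% 2 == 0)
    stop_validation("profile length must be odd and >= 3")
  if (nominal_length < n)
    stop_validation("`nominal_length` must be >= the profile length")
  lab <- slope_labels(p)
  m <- (n - 1) %/% 2
  n_up_left <- sum(lab[seq_len(m)] == 1L)
  n_down_right <- sum(lab[seq.int(m + 1, n - 1)] == -1L)
  2 * min(n_up_left, n_down_right) / (nominal_length - 1)
}

# Profile along one axis centred at `centre` (integer voxel), clipped
# symmetrically so both half-lengths shrink to the largest feasible value.
# Returns NULL when no symmetric window of half-length >= 1 exists.
extract_profile <- function(a, centre, axis, half) {
  d <- dim(a)
  h <- min(half, centre[axis] - 1L, d[axis] - centre[axis])
  if (h < 1L) return(NULL)
  idx <- lapply(1:3, function(ax) {
    if (ax == axis) seq.int(centre[ax] - h, centre[ax] + h) else centre[ax]
  })
  as.vector(a[idx[[1]], idx[[2]], idx[[3]]])
}

#' Stage 2: refine candidates by profile-shape analysis
#'
#' Extracts intensity profiles from the LEI along the three orthogonal axes
#' around each candidate (rounded to the nearest voxel), scores each with
#' [shape_score()], combines the three axis scores (arithmetic mean by
#' default, `min` as a stricter alternative) and keeps candidates whose
#' final score reaches `shape_threshold`.  The profile length is the
#' nearest odd integer to `profile_fraction * dmax`; near volume borders
#' profiles are clipped symmetrically, and an axis with no symmetric window
#' contributes a score of 0.
#'
#' @param lei The locally enhanced image, a [nuc_volume()].
#' @param candidates Centroid tibble from [stage1_candidates()].
#' @param dmax Largest nucleus diameter in voxels.
#' @param profile_fraction Profile length as a fraction of `dmax`
#'   (default 0.70).
#' @param shape_threshold Minimum final score T_S (default 0.85).
#' @param combine How to combine axis scores: `"mean"` or `"min"`.
#' @return The surviving candidates with their final scores in `score`.
#' @export
stage2_refine <- function(lei, candidates, dmax,
                          profile_fraction = 0.70,
                          shape_threshold = 0.85,
                          combine = c("mean", "min")) {
  combine <- match.arg(combine)
  if (profile_fraction <= 0 || profile_fraction > 1)
    stop_validation("`profile_fraction` must lie in (0, 1]")
  if (shape_threshold <= 0 || shape_threshold > 1)
    stop_validation("`shape_threshold` must lie in (0, 1]")
  if (nrow(candidates) == 0) return(candidates)
  a <- vol_data(lei)
  d <- dim(a)
  np <- 2L * as.integer(round((profile_fraction * dmax - 1) / 2)) + 1L
  np <- max(np, 3L)
  half <- (np - 1L) %/% 2L
  comb_fun <- if (combine == "mean") mean else min
  scores <- vapply(seq_len(nrow(candidates)), function(i) {
    centre <- pmin(pmax(as.integer(round(
      c(candidates$x[i], candidates$y[i], candidates$z[i]))), 1L), d)
    s <- vapply(1:3, function(ax) {
      p <- extract_profile(a, centre, ax, half)
      if (is.null(p)) 0 else shape_score(p, nominal_length = np)
    }, numeric(1))
    comb_fun(s)
  }, numeric(1))
  out <- candidates[scores >= shape_threshold, , drop = FALSE]
  out$score <- scores[scores >= shape_threshold]
  out
}

#' Pairwise Euclidean distances between centroids
#'
#' @param centroids A centroid tibble.
#' @return A symmetric matrix of voxel-unit distances with zero diagonal,
#'   rows/columns named by centroid label.
#' @export
pairwise_distances <- function(centroids) {
  if (nrow(centroids) < 1)
    stop_validation("need at least one centroid")
  m <- as.matrix(dist(as.matrix(centroids[, c("x", "y", "z")])))
  dimnames(m) <- list(centroids$label, centroids$label)
  m
}

#' Stage 3: merge fragmented detections
#'
#' Groups centroids by the transitive closure of "distance at most
#' `distance_threshold`" (the iterative common-group merging of fragmented
#' nuclei, implemented with a disjoint-set forest, so the result does not
#' depend on input order) and replaces each group by the unweighted mean of
#' its members' coordinates.  Labels are renumbered 1..K; the `score` of a
#' merged centroid is the mean of its members' scores.
#'
#' @param centroids A centroid tibble.
#' @param distance_threshold Merge distance T_D in voxels (> 0); the usual
#'   choice is half the largest nucleus diameter (15 at D_max = 30).
#' @return The merged centroid tibble with an `n_members` column.
#' @export
stage3_merge <- function(centroids, distance_threshold) {
  if (!is.numeric(distance_threshold) || distance_threshold <= 0)
    stop_validation("`distance_threshold` must be > 0")
  n <- nrow(centroids)
  if (n == 0) {
    out <- centroid_set()
    out$n_members <- integer()
    return(out)
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  dm <- pairwise_distances(centroids)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (dm[i, j] <= distance_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  grp <- match(root, unique(root))
  k <- max(grp)
  nmem <- tabulate(grp, k)
  msum <- function(v) rowsum(v, grp)[, 1] / nmem
  out <- centroid_set(
    x = msum(centroids$x), y = msum(centroids$y), z = msum(centroids$z),
    label = seq_len(k),
    score = if (all(is.na(centroids$score))) NA_real_ else msum(centroids$score))
  out$n_members <- nmem
  out
}
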