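# Brute-force oracles, kept deliberately independent of the package's
# implementation paths (nested loops, base R only), plus small fixtures.

# digital ball with Gaussian radial falloff on a flat background
make_ball <- function(shape, centre, radius, peak = 200, background = 5,
                      support = 2 * radius) {
  a <- array(background, shape)
  for (x in seq_len(shape[1])) for (y in seq_len(shape[2]))
    for (z in seq_len(shape[3])) {
      d2 <- sum((c(x, y, z) - centre)^2)
      if (d2 <= support^2)
        a[x, y, z] <- a[x, y, z] + peak * exp(-d2 / (2 * (radius / 2)^2))
    }
  a
}

# hard binary ball (for D_max / sphericity checks)
make_hard_ball_mask <- function(shape, centre, radius) {
  a <- array(0, shape)
  for (x in seq_len(shape[1])) for (y in seq_len(shape[2]))
    for (z in seq_len(shape[3]))
      if (sum((c(x, y, z) - centre)^2) <= radius^2) a[x, y, z] <- 1
  a
}

clamp_idx <- function(i, n) min(max(i, 1L), n)

# direct (non-separable) 3D convolution with an outer-product kernel,
# edge-replicate borders
oracle_conv3 <- function(a, kx, ky, kz) {
  d <- dim(a)
  hx <- (length(kx) - 1) / 2; hy <- (length(ky) - 1) / 2
  hz <- (length(kz) - 1) / 2
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    s <- 0
    for (ti in -hx:hx) for (tj in -hy:hy) for (tk in -hz:hz) {
      s <- s + kx[ti + hx + 1] * ky[tj + hy + 1] * kz[tk + hz + 1] *
        a[clamp_idx(i + ti, d[1]), clamp_idx(j + tj, d[2]),
          clamp_idx(k + tk, d[3])]
    }
    out[i, j, k] <- s
  }
  out
}

# direct 3D cube-mean of odd edge `len`
oracle_box3 <- function(a, len) {
  k <- rep(1 / len, len)
  oracle_conv3(a, k, k, k)
}

# direct 3D median with cubic window, edge-replicate
oracle_median3 <- function(a, h) {
  d <- dim(a)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    buf <- numeric()
    for (ti in -h:h) for (tj in -h:h) for (tk in -h:h)
      buf <- c(buf, a[clamp_idx(i + ti, d[1]), clamp_idx(j + tj, d[2]),
                      clamp_idx(k + tk, d[3])])
    out[i, j, k] <- median(buf)
  }
  out
}

# exhaustive Otsu: minimize the within-class weighted variance over all
# 255 cut points of a 256-bin histogram
oracle_otsu <- function(values, nbins = 256L) {
  rng <- range(values)
  bin <- pmin(floor((values - rng[1]) / (rng[2] - rng[1]) * nbins) + 1L, nbins)
  mids <- rng[1] + ((seq_len(nbins) - 0.5) / nbins) * (rng[2] - rng[1])
  best_t <- NA; best <- Inf
  for (t in seq_len(nbins - 1)) {
    lo <- bin <= t; hi <- !lo
    wv <- 0
    if (any(lo)) wv <- wv + sum(lo) * var_pop(mids[bin[lo]])
    if (any(hi)) wv <- wv + sum(hi) * var_pop(mids[bin[hi]])
    if (wv < best) { best <- wv; best_t <- t }
  }
  rng[1] + (best_t / nbins) * (rng[2] - rng[1])
}

var_pop <- function(x) mean((x - mean(x))^2)

# nested-loop characteristic ratio at one voxel
oracle_ratio <- function(a, voxel, nb) {
  d <- dim(a)
  h <- (nb - 1) / 2
  centre <- a[voxel[1], voxel[2], voxel[3]]
  tot <- 0; le <- 0
  for (ti in -h:h) for (tj in -h:h) for (tk in -h:h) {
    ii <- voxel[1] + ti; jj <- voxel[2] + tj; kk <- voxel[3] + tk
    if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
      next
    tot <- tot + 1
    if (a[ii, jj, kk] <= centre) le <- le + 1
  }
  le / tot
}

# brute-force transitive closure of the "within td" relation via boolean
# matrix powers; returns group index per point
oracle_closure_groups <- function(xyz, td) {
  n <- nrow(xyz)
  adj <- as.matrix(dist(xyz)) <= td
  reach <- adj
  for (rep in seq_len(n)) reach <- (reach %*% adj) > 0 | reach
  grp <- integer(n)
  g <- 0L
  for (i in seq_len(n)) {
    if (grp[i] == 0L) {
      g <- g + 1L
      grp[reach[i, ]] <- g
    }
  }
  grp
}

# tiny deterministic random volume
rand_volume <- function(shape, seed, lo = 0, hi = 100) {
  withr::with_seed(seed, array(runif(prod(shape), lo, hi), shape))
}

# small fast phantom spec for unit tests
small_spec <- function(..., shape = c(96, 96, 96), n_nuclei = 6L,
                       touching_pairs = 0L, seed = 42L) {
  synthetic_spec(shape = shape, n_nuclei = n_nuclei,
                 touching_pairs = touching_pairs, seed = seed, ...)
}
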