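#' Specification for a synthetic embryo-like volume
#'
#' Describes a phantom that emulates an early-embryo fluorescence stack:
#' bright quasi-spherical nuclei whose intensity decays as a Gaussian
#' (`sigma = radius / 2`) from the centre, occasional brighter intra-nuclear
#' fragments, a non-uniform (linear-gradient) background, additive Gaussian
#' noise, impulsive (salt-and-pepper) noise, and optionally an anisotropic
#' raw grid with coarse z sampling.  The defaults reproduce the lowest
#' time point of the imaging setting the package targets: a 261 x 261 x 224
#' near-isotropic grid holding 17 nuclei of radius 8-15 voxels (largest
#' diameter about 30 voxels).
#'
#' @param shape Volume shape in voxels.
#' @param n_nuclei Number of nuclei (ground-truth centroids).
#' @param radius_range Min/max nucleus radius in voxels (>= 3).
#' @param peak_intensity Added intensity at a nucleus centre.
#' @param background Constant background level.
#' @param background_gradient Amplitude of the linear background gradient
#'   as a fraction of `peak_intensity`.
#' @param gaussian_noise_sd Standard deviation of the additive noise.
#' @param impulse_fraction Fraction of voxels hit by impulsive noise
#'   (half set to 0, half to twice the peak).
#' @param fragments_per_nucleus Number of small bright interior blobs per
#'   nucleus (0-2); amplitude 0.15 x peak, radius r/4, offset < r/3.
#' @param min_center_gap Minimum centre-to-centre distance between
#'   non-touching nuclei, voxels.
#' @param touching_pairs Number of nucleus pairs placed in contact
#'   (centre gap = sum of radii).
#' @param anisotropic If `TRUE`, emit the raw anisotropic grid: every
#'   `z_step`-th slice at z spacing `z_step * 0.375` µm.
#' @param z_step Slice subsampling step for the anisotropic mode.
#' @param seed Integer seed; fully determines the output.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(261, 261, 224),
                           n_nuclei = 17L,
                           radius_range = c(8, 15),
                           peak_intensity = 200,
                           background = 20,
                           background_gradient = 0.15,
                           gaussian_noise_sd = 8,
                           impulse_fraction = 1e-4,
                           fragments_per_nucleus = 1L,
                           min_center_gap = 32,
                           touching_pairs = 1L,
                           anisotropic = FALSE,
                           z_step = 8L,
                           seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop_validation("`shape` must be three positive integers")
  n_nuclei <- as.integer(n_nuclei)
  if (n_nuclei < 0L) stop_validation("`n_nuclei` must be >= 0")
  radius_range <- as.numeric(radius_range)
  if (length(radius_range) != 2L || radius_range[1] < 3 ||
      radius_range[2] < radius_range[1])
    stop_validation("`radius_range` must be increasing with minimum >= 3")
  if (peak_intensity <= 0) stop_validation("`peak_intensity` must be > 0")
  if (background < 0) stop_validation("`background` must be >= 0")
  if (background_gradient < 0 || background_gradient > 1)
    stop_validation("`background_gradient` must lie in [0, 1]")
  if (gaussian_noise_sd < 0) stop_validation("`gaussian_noise_sd` must be >= 0")
  if (impulse_fraction < 0 || impulse_fraction > 1)
    stop_validation("`impulse_fraction` must lie in [0, 1]")
  fragments_per_nucleus <- as.integer(fragments_per_nucleus)
  if (fragments_per_nucleus < 0L || fragments_per_nucleus > 2L)
    stop_validation("`fragments_per_nucleus` must be 0, 1 or 2")
  if (min_center_gap <= 0) stop_validation("`min_center_gap` must be > 0")
  touching_pairs <- as.integer(touching_pairs)
  if (touching_pairs < 0L || 2L * touching_pairs > n_nuclei)
    stop_validation("`touching_pairs` must satisfy 2 * pairs <= n_nuclei")
  z_step <- as.integer(z_step)
  if (z_step < 1L) stop_validation("`z_step` must be >= 1")
  structure(list(
    shape = shape, n_nuclei = n_nuclei, radius_range = radius_range,
    peak_intensity = peak_intensity, background = background,
    background_gradient = background_gradient,
    gaussian_noise_sd = gaussian_noise_sd,
    impulse_fraction = impulse_fraction,
    fragments_per_nucleus = fragments_per_nucleus,
    min_center_gap = min_center_gap, touching_pairs = touching_pairs,
    anisotropic = anisotropic, z_step = z_step,
    seed = as.integer(seed)), class = "synthetic_spec")
}

# add amp * exp(-d^2 / (2 sigma^2)) around `centre`, truncated at `support`
paint_blob <- function(a, centre, sigma, amp, support) {
  d <- dim(a)
  lo <- pmax(floor(centre - support), 1)
  hi <- pmin(ceiling(centre + support), d)
  if (any(lo > hi)) return(a)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- (xs - centre[1])^2
  dy2 <- (ys - centre[2])^2
  dz2 <- (zs - centre[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  blob <- amp * exp(-d2 / (2 * sigma^2))
  blob[d2 > support^2] <- 0
  a[xs, ys, zs] <- a[xs, ys, zs] + blob
  a
}

#' Generate a synthetic volume with known centroids
#'
#' Realizes a [synthetic_spec()]: nuclei are placed by rejection sampling
#' (centre gap at least `min_center_gap`, except designated touching pairs
#' placed at a gap equal to the sum of their radii), painted as truncated
#' Gaussian blobs (`sigma = r / 2`, support `2 r` so the intensity decays
#' smoothly to the background), fragments and background gradient added,
#' then Gaussian and impulsive noise.  The emitted ground truth is the
#' exact continuous centre of every nucleus, in voxel coordinates of the
#' fine (near-isotropic) grid.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `volume` (a [nuc_volume()]) and `centroids` (the
#'   ground-truth tibble, including each nucleus `radius`).
#' @export
generate_embryo <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    stop_validation("`spec` must be a `synthetic_spec`")
  withr::with_seed(spec$seed, generate_embryo_impl(spec))
}

generate_embryo_impl <- function(spec) {
  d <- spec$shape
  n <- spec$n_nuclei
  radii <- if (n > 0)
    stats::runif(n, spec$radius_range[1], spec$radius_range[2]) else numeric()
  mate <- rep(NA_integer_, n)
  if (spec$touching_pairs > 0)
    for (k in seq_len(spec$touching_pairs)) {
      mate[2 * k - 1] <- 2L * k
      mate[2 * k] <- 2L * k - 1L
    }

  centres <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    r <- radii[i]
    placed <- FALSE
    for (attempt in seq_len(1e4)) {
      if (!is.na(mate[i]) && mate[i] < i) {
        # touching partner: at gap r_i + r_mate in a random direction
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        p <- centres[mate[i], ] + u * (r + radii[mate[i]])
      } else {
        p <- stats::runif(3, 1 + r, d - r)
      }
      if (any(p < 1 + r) || any(p > d - r)) next
      ok <- TRUE
      for (j in seq_len(i - 1)) {
        gap <- sqrt(sum((p - centres[j, ])^2))
        need <- if (!is.na(mate[i]) && mate[i] == j)
          0 else if (!is.na(mate[i])) radii[i] + radii[j]
        else spec$min_center_gap
        if (gap < need) { ok <- FALSE; break }
      }
      if (ok) { centres[i, ] <- p; placed <- TRUE; break }
    }
    if (!placed)
      stop_validation("infeasible synthetic spec: nucleus placement failed")
  }

  # background: constant level plus a linear gradient along a random direction
  a <- array(spec$background, d)
  if (spec$background_gradient > 0) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    proj <- outer(outer(u[1] * seq_len(d[1]), u[2] * seq_len(d[2]), "+"),
                  u[3] * seq_len(d[3]), "+")
    proj <- (proj - min(proj)) / max(max(proj) - min(proj), 1e-12)
    a <- a + spec$background_gradient * spec$peak_intensity * proj
  }

  for (i in seq_len(n)) {
    r <- radii[i]
    a <- paint_blob(a, centres[i, ], r / 2, spec$peak_intensity, 2 * r)
    for (f in seq_len(spec$fragments_per_nucleus)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      fc <- centres[i, ] + u * stats::runif(1, 0, r / 3)
      a <- paint_blob(a, fc, r / 8, 0.15 * spec$peak_intensity, r / 2)
    }
  }

  if (spec$gaussian_noise_sd > 0)
    a <- a + stats::rnorm(length(a), 0, spec$gaussian_noise_sd)
  if (spec$impulse_fraction > 0) {
    m <- round(spec$impulse_fraction * length(a))
    if (m > 0) {
      hit <- sample.int(length(a), m)
      half <- seq_len(m) <= m / 2
      a[hit[half]] <- 0
      a[hit[!half]] <- 2 * spec$peak_intensity
    }
  }
  a <- pmax(a, 0)

  gt <- centroid_set(x = centres[, 1], y = centres[, 2], z = centres[, 3],
                     label = seq_len(n))
  gt$radius <- radii
  if (spec$anisotropic) {
    keep <- seq(1, d[3], by = spec$z_step)
    vol <- nuc_volume(array(a[, , keep], c(d[1], d[2], length(keep))),
                      c(0.385, 0.385, 0.375 * spec$z_step))
  } else {
    vol <- nuc_volume(array(a, d), c(0.385, 0.385, 0.375))
  }
  list(volume = vol, centroids = gt)
}
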