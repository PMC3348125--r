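#' Filter lengths for multiscale cube filtering
#'
#' Derives the odd cube-filter edge lengths from the largest nucleus
#' diameter: each fraction of `dmax` is rounded to the nearest odd integer
#' (ties toward the smaller), clamped to at least 3 and at most `dmax`
#' rounded up to odd; duplicates are removed and the result sorted.
#'
#' @param dmax Largest nucleus diameter in voxels (>= 3).
#' @param fractions Fractions of `dmax` in (0, 1]; default `c(0.3, 0.5, 0.7)`.
#' @return Sorted integer vector of odd filter lengths.
#' @export
scale_lengths <- function(dmax, fractions = c(0.3, 0.5, 0.7)) {
  if (!is.numeric(dmax) || length(dmax) != 1 || dmax < 3)
    stop_validation("`dmax` must be a single value >= 3")
  fractions <- as.numeric(fractions)
  if (length(fractions) == 0)
    stop_validation("`fractions` must be non-empty")
  if (any(fractions <= 0 | fractions > 1))
    stop_validation("`fractions` must lie in (0, 1]")
  nearest_odd <- function(x) 2L * as.integer(round((x - 1) / 2)) + 1L
  upper <- nearest_odd(ceiling(dmax) + (ceiling(dmax) %% 2 == 0))
  len <- pmin(pmax(nearest_odd(fractions * dmax), 3L), upper)
  sort(unique(len))
}

#' Separable cube (box) mean filter
#'
#' Convolves the volume with a normalized cube-mean kernel of odd edge
#' `length`, implemented as three sequential 1D mean passes (x, then y,
#' then z) with edge-replicate borders — equivalent to direct 3D cube-mean
#' convolution but three scans of the stack instead of one cubic-cost scan.
#'
#' @param v A [nuc_volume()] or 3D array.
#' @param length Odd kernel edge in voxels (>= 1).
#' @return A [nuc_volume()] with the filtered intensities.
#' @export
box_filter_separable <- function(v, length) {
  a <- vol_data(v)
  length <- as.integer(length)
  if (is.na(length) || length < 1L || length %% 2L == 0L)
    stop_validation("`length` must be an odd integer >= 1")
  if (length == 1L) return(nuc_volume(a, vol_spacing(v)))
  d <- dim(a)
  k <- rep(1 / length, length)
  out <- as.vector(a)
  for (ax in 1:3) out <- conv1d_axis_cpp(out, d, k, ax - 1L)
  nuc_volume(array(out, d), vol_spacing(v))
}

#' Locally enhanced image (LEI) by multiscale cube filtering
#'
#' Computes the cube-mean response at every scale and takes the voxelwise
#' maximum, so each voxel carries the response of the best-matching nucleus
#' size.  When a candidate mask is supplied (candidate-region processing),
#' responses are computed everywhere but the LEI is retained only on
#' non-zero mask voxels and set to 0 elsewhere.
#'
#' @param v A [nuc_volume()] (preprocessed image, or the hybrid image for
#'   candidate-region processing).
#' @param lengths Odd filter lengths from [scale_lengths()].
#' @param mask Optional binary array / `nuc_mask` restricting the output.
#' @return The LEI as a [nuc_volume()].
#' @export
local_enhance <- function(v, lengths, mask = NULL) {
  a <- vol_data(v)
  lengths <- as.integer(lengths)
  if (length(lengths) == 0)
    stop_validation("`lengths` must be non-empty")
  lei <- NULL
  for (len in lengths) {
    resp <- vol_data(box_filter_separable(a, len))
    lei <- if (is.null(lei)) resp else pmax(lei, resp)
  }
  if (!is.null(mask)) {
    mk <- if (inherits(mask, "nuc_mask")) mask$mask else mask
    if (!identical(dim(mk), dim(a)))
      stop_validation("mask shape differs from volume shape")
    lei <- lei * (mk != 0)
  }
  nuc_volume(array(lei, dim(a)), vol_spacing(v))
}
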