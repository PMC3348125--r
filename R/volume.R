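#' Construct a 3D intensity volume
#'
#' A `nuc_volume` bundles a 3D array of non-negative intensities with the
#' per-axis voxel spacing in micrometres.  The array is indexed `[x, y, z]`
#' with `z` the slice axis; all coordinates used by the package are 1-based
#' voxel indices on this grid (fractional values allowed for centroids).
#'
#' @param data A numeric 3D array of finite, non-negative intensities.
#' @param spacing Numeric length-3 vector of voxel sizes in µm, one per axis.
#'   The default is the raw confocal grid `(0.385, 0.385, 3)` µm.
#' @return An object of class `nuc_volume`: a list with elements `data`
#'   (the array) and `spacing`.
#' @examples
#' v <- nuc_volume(array(runif(8 * 8 * 4), c(8, 8, 4)), spacing = c(1, 1, 1))
#' dim(v)
#' @export
nuc_volume <- function(data, spacing = c(0.385, 0.385, 3)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_validation("`data` must be a 3D array")
  if (!is.numeric(data))
    stop_validation("`data` must be numeric")
  if (anyNA(data) || any(!is.finite(data)))
    stop_validation("volume intensities must be finite")
  if (any(data < 0))
    stop_validation("volume intensities must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_validation("`spacing` must be three positive values (µm)")
  structure(list(data = data, spacing = spacing), class = "nuc_volume")
}

#' @export
dim.nuc_volume <- function(x) dim(x$data)

#' @export
range.nuc_volume <- function(..., na.rm = FALSE) {
  range(..1$data, na.rm = na.rm)
}

#' @export
print.nuc_volume <- function(x, ...) {
  d <- dim(x$data)
  r <- range(x$data)
  cat(sprintf(
    "<nuc_volume> %d x %d x %d voxels, spacing %.3f x %.3f x %.3f um, intensities [%.3g, %.3g]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], r[1], r[2]))
  invisible(x)
}

#' @export
as.array.nuc_volume <- function(x, ...) x$data

# Accept either a nuc_volume or a bare 3D array; return the array.
vol_data <- function(v) {
  if (inherits(v, "nuc_volume")) v$data
  else if (is.array(v) && length(dim(v)) == 3L) v
  else stop_validation("expected a `nuc_volume` or a 3D array")
}

vol_spacing <- function(v, default = c(1, 1, 1)) {
  if (inherits(v, "nuc_volume")) v$spacing else default
}

#' Plot one z-slice of a volume
#'
#' Renders a single slice of a `nuc_volume` as a ggplot raster, optionally
#' overlaying centroids whose rounded z-coordinate falls on that slice.
#'
#' @param v A [nuc_volume()].
#' @param z Slice index (1-based).
#' @param centroids Optional centroid tibble with columns `x`, `y`, `z`.
#' @return A ggplot object.
#' @export
plot_slice <- function(v, z = 1L, centroids = NULL) {
  a <- vol_data(v)
  z <- as.integer(z)
  if (z < 1L || z > dim(a)[3])
    stop_validation("slice index out of range")
  sl <- a[, , z]
  df <- tibble(
    x = rep(seq_len(nrow(sl)), times = ncol(sl)),
    y = rep(seq_len(ncol(sl)), each = nrow(sl)),
    intensity = as.vector(sl))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("z = %d", z))
  if (!is.null(centroids) && nrow(centroids) > 0) {
    on_slice <- centroids[round(centroids$z) == z, , drop = FALSE]
    if (nrow(on_slice) > 0)
      p <- p + ggplot2::geom_point(
        data = on_slice, ggplot2::aes(x = .data$x, y = .data$y),
        colour = "red", shape = 3, size = 3)
  }
  p
}

#' @importFrom rlang .data
NULL
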