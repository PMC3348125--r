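#' Read a multi-page TIFF z-stack
#'
#' Reads an 8- or 16-bit grayscale multi-page TIFF into a [nuc_volume()],
#' with the page index becoming the z axis.  Intensities are kept on their
#' stored integer scale.
#'
#' @param path Path to the TIFF file.
#' @param spacing Voxel spacing in µm (x, y, z); defaults to the raw
#'   confocal grid `(0.385, 0.385, 3)`.
#' @return A [nuc_volume()] of shape `nx x ny x n_pages`.
#' @export
read_stack <- function(path, spacing = c(0.385, 0.385, 3)) {
  if (!file.exists(path))
    stop_validation(sprintf("file not found: %s", path))
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) stop_validation(
      sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop_validation("TIFF pages have inconsistent shapes")
  if (any(vapply(pages, function(p) length(dim(p)) > 2 && dim(p)[3] > 1, logical(1))))
    stop_validation("multi-channel TIFF pages are not supported")
  nz <- length(pages)
  ny <- shapes[1, 1]   # readTIFF rows are image rows (y)
  nx <- shapes[2, 1]
  arr <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    arr[, , k] <- t(pg)
  }
  nuc_volume(arr, spacing)
}

#' Write a volume as a multi-page TIFF
#'
#' Stores intensities as 16-bit (or 8-bit) grayscale pages.  Values are
#' rounded to integers; they must already lie within the representable
#' range `[0, 2^bits - 1]`.
#'
#' @param v A [nuc_volume()] or 3D array.
#' @param path Output file path.
#' @param bits Bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(v, path, bits = 16L) {
  a <- vol_data(v)
  if (!bits %in% c(8L, 16L))
    stop_validation("`bits` must be 8 or 16")
  maxv <- 2^bits - 1
  if (min(a) < 0 || max(a) > maxv)
    stop_validation(sprintf("intensities must lie in [0, %d] for %d-bit output",
                            maxv, bits))
  pages <- lapply(seq_len(dim(a)[3]), function(k) t(round(a[, , k])) / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Resample a stack to near-isotropic voxels by cubic z-interpolation
#'
#' Each (x, y) column is interpolated along z with a cubic spline, producing
#' `factor` output slices per input slice so that the z spacing shrinks by
#' `factor` (e.g. 28 raw slices at 3 µm become 224 slices at 0.375 µm for
#' `factor = 8`).  Output slice `1` coincides with input slice `1`; output
#' positions beyond the last input slice replicate it.  Interpolated
#' intensities are clamped to the input intensity range so the spline cannot
#' overshoot at sharp transitions.
#'
#' @param v A [nuc_volume()].
#' @param factor Integer upsampling factor along z (>= 1).
#' @return A [nuc_volume()] with `dim[3] * factor` slices and z spacing
#'   divided by `factor`.
#' @export
interpolate_isotropic <- function(v, factor) {
  a <- vol_data(v)
  sp <- vol_spacing(v)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop_validation("`factor` must be an integer >= 1")
  if (factor == 1L) return(nuc_volume(a, sp))
  d <- dim(a)
  nz <- d[3]
  nzo <- nz * factor
  rng <- range(a)
  if (nz == 1L) {
    out <- array(a, c(d[1], d[2], nzo))
    return(nuc_volume(out, c(sp[1], sp[2], sp[3] / factor)))
  }
  xin <- seq_len(nz)
  xout <- pmin((seq_len(nzo) - 1) / factor + 1, nz)
  # one spline per (x, y) column; "fmm" reproduces cubic polynomials exactly
  m <- matrix(a, nrow = d[1] * d[2], ncol = nz)
  om <- matrix(0, nrow = d[1] * d[2], ncol = nzo)
  for (r in seq_len(nrow(m))) {
    om[r, ] <- spline(xin, m[r, ], xout = xout, method = "fmm")$y
  }
  om <- pmin(pmax(om, rng[1]), rng[2])
  nuc_volume(array(om, c(d[1], d[2], nzo)), c(sp[1], sp[2], sp[3] / factor))
}

#' Create a centroid table
#'
#' Centroid sets are plain tibbles with columns `label` (unique positive
#' integers), `x`, `y`, `z` (1-based fractional voxel coordinates) and an
#' optional `score` in `[0, 1]`.
#'
#' @param x,y,z Numeric coordinate vectors of equal length.
#' @param label Integer labels; defaults to `1:n`.
#' @param score Optional numeric scores.
#' @return A tibble with columns `label`, `x`, `y`, `z`, `score`.
#' @export
centroid_set <- function(x = numeric(), y = numeric(), z = numeric(),
                         label = seq_along(x), score = NA_real_) {
  out <- tibble(label = as.integer(label), x = as.numeric(x),
                y = as.numeric(y), z = as.numeric(z),
                score = as.numeric(score))
  if (anyDuplicated(out$label))
    stop_validation("centroid labels must be unique")
  out
}

#' Write centroids to CSV
#'
#' @param centroids A centroid tibble (see [centroid_set()]).
#' @param path Output CSV path; columns `label,x,y,z,score`.
#' @return `path`, invisibly.
#' @export
write_centroids <- function(centroids, path) {
  cols <- c("label", "x", "y", "z")
  if (!all(cols %in% names(centroids)))
    stop_validation("centroid table needs columns label, x, y, z")
  if (!"score" %in% names(centroids)) centroids$score <- NA_real_
  readr::write_csv(centroids[, c(cols, "score")], path)
  invisible(path)
}

#' Read centroids from CSV
#'
#' Reads a `label,x,y,z,score` table written by [write_centroids()].  If a
#' volume shape is supplied, an `in_bounds` column flags rows whose
#' coordinates fall outside `[1, dim]` on any axis (the read still
#' succeeds; a warning is raised).
#'
#' @param path CSV path.
#' @param shape Optional integer length-3 volume shape used for bounds
#'   validation.
#' @return A centroid tibble.
#' @export
read_centroids <- function(path, shape = NULL) {
  if (!file.exists(path))
    stop_validation(sprintf("file not found: %s", path))
  df <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(
      label = readr::col_integer(), x = readr::col_double(),
      y = readr::col_double(), z = readr::col_double(),
      score = readr::col_double())),
    error = function(e) stop_validation(
      sprintf("malformed centroid CSV '%s': %s", path, conditionMessage(e))))
  if (!all(c("label", "x", "y", "z") %in% names(df)))
    stop_validation("centroid CSV must have columns label,x,y,z")
  if (anyDuplicated(df$label))
    stop_validation("duplicate centroid labels in CSV")
  if (!is.null(shape)) {
    shape <- as.integer(shape)
    df$in_bounds <- df$x >= 1 & df$x <= shape[1] &
      df$y >= 1 & df$y <= shape[2] &
      df$z >= 1 & df$z <= shape[3]
    if (any(!df$in_bounds))
      warn(sprintf("%d centroid(s) outside the stated volume bounds",
                   sum(!df$in_bounds)))
  }
  df
}
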