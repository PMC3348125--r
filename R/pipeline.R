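#' Run the full centroid-extraction pipeline
#'
#' Composes the whole method: Gaussian + median smoothing on the raw grid
#' (anisotropic kernels), cubic z-interpolation to near-isotropic voxels
#' when the input grid is anisotropic, optional candidate-region restriction
#' (variant 2: Otsu mask + hybrid image), multiscale cube-filter enhancement,
#' then the three extraction stages — characteristic-ratio candidates,
#' profile-shape refinement, and fragment merging.
#'
#' @param v Input [nuc_volume()] (raw stack).
#' @param config A [nuc_config()]; defaults reproduce the standard parameter
#'   set (T_R = 0.97, T_S = 0.85, T_D = 15 at D_max = 30).
#' @param keep_lei If `TRUE`, the locally enhanced image is stored on the
#'   result (for inspection or export).
#' @param quiet If `TRUE`, suppress the per-stage count messages.
#' @return An object of class `nuc_detection` with elements `centroids`
#'   (final tibble), `counts` (named stage-1/2/3 candidate counts), `config`,
#'   `shape` (processed volume shape) and optionally `lei`.  Use [tidy()] for
#'   the centroid table and [glance()] for the per-stage counts.
#' @export
run_pipeline <- function(v, config = nuc_config(), keep_lei = FALSE,
                         quiet = FALSE) {
  if (!inherits(config, "nuc_config")) config <- do.call(nuc_config, config)
  say <- function(...) if (!quiet) message(sprintf(...))

  pre <- smooth_volume(v, config$preprocess$sigma_phys,
                       config$preprocess$median_size)
  sp <- vol_spacing(pre)
  factor <- config$interp$factor
  if (is.null(factor)) {
    factor <- max(1L, as.integer(round(sp[3] / sp[1])))
  }
  if (factor > 1L) {
    say("interpolating z by factor %d (%d -> %d slices)", factor,
        dim(pre)[3], dim(pre)[3] * factor)
    pre <- interpolate_isotropic(pre, factor)
  }

  mask <- NULL
  base <- pre
  if (config$variant == 2L) {
    cand <- tryCatch(otsu_candidates(pre), nuclei3d_degenerate = function(e) NULL)
    if (is.null(cand)) {
      warn("degenerate (constant) volume: no candidate regions; empty result")
      empty <- centroid_set()
      empty$n_members <- integer()
      return(structure(list(
        centroids = empty,
        counts = c(stage1 = 0L, stage2 = 0L, stage3 = 0L),
        config = config, shape = dim(pre), lei = NULL),
        class = "nuc_detection"))
    }
    mask <- cand$mask
    base <- hybrid_image(pre, cand)
    say("candidate regions: %d voxels above threshold %.4g",
        sum(mask), cand$threshold_used)
  }

  lengths <- scale_lengths(config$msf$dmax, config$msf$fractions)
  say("multiscale filtering at lengths %s", paste(lengths, collapse = ", "))
  lei <- local_enhance(base, lengths, mask = mask)

  s1 <- withCallingHandlers(
    stage1_candidates(lei, config$stage1$neighborhood,
                      config$stage1$ratio_threshold),
    warning = function(w) if (quiet) invokeRestart("muffleWarning"))
  s2 <- stage2_refine(lei, s1, config$msf$dmax,
                      config$stage2$profile_fraction,
                      config$stage2$shape_threshold,
                      config$stage2$combine)
  td <- config$stage3$distance_threshold %||% (0.5 * config$msf$dmax)
  s3 <- stage3_merge(s2, td)
  say("stage counts: %d -> %d -> %d", nrow(s1), nrow(s2), nrow(s3))

  structure(list(
    centroids = s3,
    counts = c(stage1 = nrow(s1), stage2 = nrow(s2), stage3 = nrow(s3)),
    config = config, shape = dim(lei),
    lei = if (keep_lei) lei else NULL),
    class = "nuc_detection")
}

#' @export
print.nuc_detection <- function(x, ...) {
  cat(sprintf(
    "<nuc_detection> variant %d, %d final centroids (stages: %d -> %d -> %d)\n",
    x$config$variant, nrow(x$centroids),
    x$counts["stage1"], x$counts["stage2"], x$counts["stage3"]))
  print(x$centroids, n = 5)
  invisible(x)
}

#' Tidy the final centroid table of a detection
#'
#' @param x A `nuc_detection` from [run_pipeline()].
#' @param ... Unused.
#' @return The final centroid tibble.
#' @method tidy nuc_detection
#' @export
tidy.nuc_detection <- function(x, ...) x$centroids

#' One-row summary of a detection run
#'
#' @param x A `nuc_detection` from [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble with the variant and the stage-1/2/3 counts.
#' @method glance nuc_detection
#' @export
glance.nuc_detection <- function(x, ...) {
  tibble(variant = x$config$variant,
         n_stage1 = x$counts[["stage1"]],
         n_stage2 = x$counts[["stage2"]],
         n_stage3 = x$counts[["stage3"]])
}

#' Plot detected centroids
#'
#' Scatter of final centroids in the x-y plane, coloured by depth (z).
#'
#' @param object A `nuc_detection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nuc_detection
#' @export
autoplot.nuc_detection <- function(object, ...) {
  ggplot2::ggplot(object$centroids,
                  ggplot2::aes(x = .data$x, y = .data$y, colour = .data$z)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::coord_fixed(xlim = c(1, object$shape[1]),
                         ylim = c(1, object$shape[2])) +
    ggplot2::labs(title = sprintf("%d detected centroids",
                                  nrow(object$centroids)),
                  colour = "z (voxel)")
}
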