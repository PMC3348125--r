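default_config <- function() {
  list(
    variant = 1L,
    preprocess = list(sigma_phys = 0.77, median_size = 3L),
    interp = list(factor = NULL),   # NULL = round(dz / dx) when anisotropic
    msf = list(dmax = 30, fractions = c(0.3, 0.5, 0.7)),
    stage1 = list(neighborhood = 7L, ratio_threshold = 0.97),
    stage2 = list(profile_fraction = 0.70, shape_threshold = 0.85,
                  combine = "mean"),
    stage3 = list(distance_threshold = NULL),  # NULL = 0.5 * dmax
    eval = list(radius = 10)
  )
}

check_range <- function(value, name, lo, hi, lo_open = TRUE) {
  bad <- !is.numeric(value) || length(value) < 1 || anyNA(value) ||
    any(if (lo_open) value <= lo else value < lo) || any(value > hi)
  if (bad)
    stop_validation(sprintf("`%s` must lie in %s%g, %g]", name,
                            if (lo_open) "(" else "[", lo, hi))
  invisible(value)
}

validate_config <- function(cfg) {
  defaults <- default_config()
  extra <- setdiff(names(cfg), names(defaults))
  if (length(extra) > 0)
    stop_validation(sprintf("unknown config key(s): %s",
                            paste(extra, collapse = ", ")))
  for (sec in names(defaults)) {
    if (is.list(defaults[[sec]])) {
      extra <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
      if (length(extra) > 0)
        stop_validation(sprintf("unknown config key(s) in `%s`: %s", sec,
                                paste(extra, collapse = ", ")))
    }
  }
  if (!cfg$variant %in% c(1L, 2L))
    stop_validation("`variant` must be 1 or 2")
  check_range(cfg$preprocess$sigma_phys, "preprocess.sigma_phys", 0, Inf)
  ms <- cfg$preprocess$median_size
  if (!is.numeric(ms) || ms < 1 || ms %% 2 == 0)
    stop_validation("`preprocess.median_size` must be an odd integer >= 1")
  if (!is.null(cfg$interp$factor) &&
      (!is.numeric(cfg$interp$factor) || cfg$interp$factor < 1))
    stop_validation("`interp.factor` must be an integer >= 1")
  if (!is.numeric(cfg$msf$dmax) || cfg$msf$dmax < 3)
    stop_validation("`msf.dmax` must be >= 3")
  check_range(cfg$msf$fractions, "msf.fractions", 0, 1)
  nb <- cfg$stage1$neighborhood
  if (!is.numeric(nb) || nb < 3 || nb %% 2 == 0)
    stop_validation("`stage1.neighborhood` must be an odd integer >= 3")
  check_range(cfg$stage1$ratio_threshold, "stage1.ratio_threshold", 0, 1)
  check_range(cfg$stage2$profile_fraction, "stage2.profile_fraction", 0, 1)
  check_range(cfg$stage2$shape_threshold, "stage2.shape_threshold", 0, 1)
  if (!cfg$stage2$combine %in% c("mean", "min"))
    stop_validation("`stage2.combine` must be \"mean\" or \"min\"")
  if (!is.null(cfg$stage3$distance_threshold))
    check_range(cfg$stage3$distance_threshold, "stage3.distance_threshold",
                0, Inf)
  check_range(cfg$eval$radius, "eval.radius", 0, Inf)
  cfg
}

# recursive defaults <- overrides merge; unknown keys surface in validation
merge_config <- function(defaults, overrides) {
  for (k in names(overrides)) {
    if (is.list(defaults[[k]]) && is.list(overrides[[k]]))
      defaults[[k]] <- merge_config(defaults[[k]], overrides[[k]])
    else defaults[[k]] <- overrides[[k]]
  }
  defaults
}

#' Pipeline configuration
#'
#' Builds the full pipeline configuration with every tunable at its default:
#' variant 1; Gaussian scale 0.77 µm (a 5 x 5 x 3 kernel at the raw confocal
#' resolution) and a 3 x 3 x 3 median; multiscale fractions (0.3, 0.5, 0.7)
#' of D_max = 30; Stage-1 neighbourhood 7 with ratio threshold T_R = 0.97;
#' Stage-2 profile fraction 0.70 with shape threshold T_S = 0.85; Stage-3
#' distance threshold T_D = 0.5 * D_max (15 voxels); matching radius 10.
#'
#' @param ... Named overrides: either top-level keys (`variant`) or section
#'   lists such as `stage1 = list(ratio_threshold = 0.95)`.  Unknown keys
#'   and out-of-range thresholds are rejected.
#' @return A validated config list of class `nuc_config`.
#' @examples
#' cfg <- nuc_config(variant = 2, stage2 = list(combine = "min"))
#' cfg$stage1$ratio_threshold
#' @export
nuc_config <- function(...) {
  overrides <- list(...)
  if (length(overrides) > 0 &&
      (is.null(names(overrides)) || any(names(overrides) == "")))
    stop_validation("all config overrides must be named")
  cfg <- merge_config(default_config(), overrides)
  cfg <- validate_config(cfg)
  structure(cfg, class = "nuc_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a (possibly partial) YAML file, fills in defaults for missing keys,
#' validates, and echoes the effective configuration.
#'
#' @param path Path to a YAML config file; sections mirror [nuc_config()]
#'   (`preprocess:`, `msf:`, `stage1:`, `stage2:`, `stage3:`, `eval:`,
#'   `interp:`, plus top-level `variant`).
#' @param quiet If `TRUE`, do not echo the effective configuration.
#' @return A validated config list of class `nuc_config`.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path))
    stop_validation(sprintf("config file not found: %s", path))
  overrides <- yaml::read_yaml(path)
  if (is.null(overrides)) overrides <- list()
  cfg <- do.call(nuc_config, overrides)
  if (!quiet)
    message("effective config:\n", yaml::as.yaml(unclass(cfg)))
  cfg
}

#' @export
print.nuc_config <- function(x, ...) {
  cat("<nuc_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
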