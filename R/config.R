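#' Analysis configuration
#'
#' Collects and validates every tunable of the morphometric pipeline. The
#' defaults reproduce the reference workflow: Otsu thresholding of the
#' hematoxylin (nuclear) map, a 7-pixel Euclidean perinuclear ring,
#' watershed splitting of touching nuclei, and exclusion of border-truncated
#' nuclei.
#'
#' @param ring_width_px Positive integer; perinuclear ring width in pixels
#'   (Euclidean distance from the nuclear boundary). Default 7.
#' @param threshold_method `"otsu"` (parameter-free, default) or `"fixed"`.
#' @param fixed_threshold Threshold on the nuclear map in \[0,1\]; required
#'   if and only if `threshold_method = "fixed"`.
#' @param min_nucleus_area_px Nonnegative integer; objects smaller than this
#'   are discarded as debris. Default 50.
#' @param max_nucleus_area_px Optional integer upper area bound; must exceed
#'   `min_nucleus_area_px` when set.
#' @param split_touching Split touching nuclei by distance-transform
#'   watershed. Default `TRUE`.
#' @param exclude_border Drop nuclei touching the image border (their area is
#'   censored). Default `TRUE`.
#' @param log_constant_k Positive constant `k` of the log enhancement
#'   `log(1 + k*x) / log(1 + k)`. Default 255.
#' @param intensity_statistic Which perinuclear statistic downstream
#'   reporting favours: `"mean"` (default) or `"integrated"`; both are always
#'   computed per cell.
#' @param seed Optional integer seed recorded in run manifests.
#'
#' @return An object of class `"analysis_config"` (a validated named list).
#' @examples
#' cfg <- analysis_config(ring_width_px = 7)
#' cfg$threshold_method
#' @export
analysis_config <- function(ring_width_px = 7L,
                            threshold_method = c("otsu", "fixed"),
                            fixed_threshold = NULL,
                            min_nucleus_area_px = 50L,
                            max_nucleus_area_px = NULL,
                            split_touching = TRUE,
                            exclude_border = TRUE,
                            log_constant_k = 255,
                            intensity_statistic = c("mean", "integrated"),
                            seed = NULL) {
  threshold_method <- match.arg(threshold_method)
  intensity_statistic <- match.arg(intensity_statistic)

  ring_width_px <- as.integer(ring_width_px)
  if (length(ring_width_px) != 1L || is.na(ring_width_px) ||
      ring_width_px < 1L)
    stop("ring_width_px must be a positive integer (>= 1)")
  min_nucleus_area_px <- as.integer(min_nucleus_area_px)
  if (length(min_nucleus_area_px) != 1L || is.na(min_nucleus_area_px) ||
      min_nucleus_area_px < 0L)
    stop("min_nucleus_area_px must be a nonnegative integer")
  if (!is.null(max_nucleus_area_px)) {
    max_nucleus_area_px <- as.integer(max_nucleus_area_px)
    if (is.na(max_nucleus_area_px) ||
        min_nucleus_area_px >= max_nucleus_area_px)
      stop("max_nucleus_area_px must exceed min_nucleus_area_px")
  }
  if (threshold_method == "fixed") {
    if (is.null(fixed_threshold))
      stop("fixed_threshold is required when threshold_method = \"fixed\"")
    fixed_threshold <- as.numeric(fixed_threshold)
    if (length(fixed_threshold) != 1L || is.na(fixed_threshold) ||
        fixed_threshold < 0 || fixed_threshold > 1)
      stop("fixed_threshold must lie in [0, 1]")
  } else if (!is.null(fixed_threshold)) {
    stop("fixed_threshold is only meaningful with threshold_method = \"fixed\"")
  }
  log_constant_k <- as.numeric(log_constant_k)
  if (length(log_constant_k) != 1L || !is.finite(log_constant_k) ||
      log_constant_k <= 0)
    stop("log_constant_k must be a positive number")
  if (!is.logical(split_touching) || length(split_touching) != 1L ||
      is.na(split_touching))
    stop("split_touching must be TRUE or FALSE")
  if (!is.logical(exclude_border) || length(exclude_border) != 1L ||
      is.na(exclude_border))
    stop("exclude_border must be TRUE or FALSE")
  if (!is.null(seed)) seed <- as.integer(seed)

  structure(list(ring_width_px = ring_width_px,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_nucleus_area_px = min_nucleus_area_px,
                 max_nucleus_area_px = max_nucleus_area_px,
                 split_touching = split_touching,
                 exclude_border = exclude_border,
                 log_constant_k = log_constant_k,
                 intensity_statistic = intensity_statistic,
                 seed = seed),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' The YAML keys mirror the [analysis_config()] argument names; absent keys
#' take their defaults, unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return An `"analysis_config"`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  thr <- if (x$threshold_method == "fixed")
    sprintf("fixed (%.4f)", x$fixed_threshold) else "otsu"
  cat(sprintf("  ring width:      %d px (Euclidean)\n", x$ring_width_px))
  cat(sprintf("  threshold:       %s\n", thr))
  cat(sprintf("  nucleus area:    [%d, %s] px\n", x$min_nucleus_area_px,
              if (is.null(x$max_nucleus_area_px)) "Inf"
              else x$max_nucleus_area_px))
  cat(sprintf("  split touching:  %s   exclude border: %s\n",
              x$split_touching, x$exclude_border))
  cat(sprintf("  log constant k:  %g\n", x$log_constant_k))
  cat(sprintf("  intensity stat:  %s\n", x$intensity_statistic))
  invisible(x)
}
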