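#' Pipeline run configuration
#'
#' Collects every tunable of the three stages so a result can embed the
#' exact configuration that produced it. The configuration round-trips
#' losslessly through YAML/JSON via [trs_config_from_list()].
#'
#' @param enhancement an [enhancement_config()].
#' @param no_enhance bypass stage 1 entirely (ablation switch).
#' @param levels number of intensity classes M within the ROI (2..4).
#' @param alpha trim fraction of the class statistics, \[0, 0.5).
#' @param bins histogram bins for the ROI intensity range.
#' @param printed_eq1 use the linear (unsquared) between-class criterion
#'   form; comparison only, see [between_class_variance()].
#' @param box_sizes explicit box-size schedule, or `NULL` for the dyadic
#'   default derived from the ROI extent.
#' @param n_offsets box-counting grid offsets (1 or 4).
#' @param min_roi_pixels slices with fewer mask pixels are skipped.
#' @param window_center,window_width window/level used to map HU-valued
#'   volumes to \[0, 1\] on read (soft-tissue default 40/400).
#' @param seed optional integer recorded with the run.
#' @return A `trs_config` list with blocks `enhancement`, `segmentation`,
#'   `roughness`, `io`, `seed`.
#' @export
trs_config <- function(enhancement = enhancement_config(),
                       no_enhance = FALSE,
                       levels = 3, alpha = 0.1, bins = 256,
                       printed_eq1 = FALSE,
                       box_sizes = NULL, n_offsets = 4, min_roi_pixels = 16,
                       window_center = 40, window_width = 400,
                       seed = NULL) {
  stopifnot(inherits(enhancement, "trs_enhancement_config"))
  if (levels < 2 || levels > 4) stop("levels must be 2..4", call. = FALSE)
  if (alpha < 0 || alpha >= 0.5) stop("alpha must be in [0, 0.5)", call. = FALSE)
  structure(
    list(
      enhancement = list(enabled = !no_enhance, config = enhancement),
      segmentation = list(levels = as.integer(levels), alpha = alpha,
                          bins = as.integer(bins),
                          printed_eq1 = isTRUE(printed_eq1)),
      roughness = list(box_sizes = box_sizes,
                       n_offsets = as.integer(n_offsets),
                       min_roi_pixels = as.integer(min_roi_pixels)),
      io = list(window_center = window_center, window_width = window_width),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "trs_config"
  )
}

#' Serialize / deserialize a run configuration
#'
#' @param config a `trs_config`.
#' @return `trs_config_to_list()` gives a plain nested list suitable for
#'   `yaml::as.yaml()` or `jsonlite::toJSON()`; `trs_config_from_list()`
#'   rebuilds the identical `trs_config`.
#' @export
trs_config_to_list <- function(config) {
  stopifnot(inherits(config, "trs_config"))
  e <- config$enhancement$config
  list(
    enhancement = list(
      enabled = config$enhancement$enabled,
      guided_radius = e$guided_radius, guided_epsilon = e$guided_epsilon,
      edge_gain = e$edge_gain, fusion_weights = e$fusion_weights,
      roi_dilation = e$roi_dilation),
    segmentation = config$segmentation,
    roughness = config$roughness,
    io = config$io,
    seed = config$seed
  )
}

#' @param x a nested list as produced by [trs_config_to_list()] (e.g. parsed
#'   back from YAML/JSON).
#' @rdname trs_config_to_list
#' @export
trs_config_from_list <- function(x) {
  e <- x$enhancement
  trs_config(
    enhancement = enhancement_config(
      guided_radius = e$guided_radius, guided_epsilon = e$guided_epsilon,
      edge_gain = e$edge_gain, fusion_weights = unlist(e$fusion_weights),
      roi_dilation = e$roi_dilation),
    no_enhance = !isTRUE(e$enabled),
    levels = x$segmentation$levels, alpha = x$segmentation$alpha,
    bins = x$segmentation$bins, printed_eq1 = x$segmentation$printed_eq1,
    box_sizes = if (length(x$roughness$box_sizes)) unlist(x$roughness$box_sizes) else NULL,
    n_offsets = x$roughness$n_offsets,
    min_roi_pixels = x$roughness$min_roi_pixels,
    window_center = x$io$window_center, window_width = x$io$window_width,
    seed = x$seed
  )
}

#' @export
print.trs_config <- function(x, ...) {
  cat("<trs_config>\n")
  cat(yaml::as.yaml(trs_config_to_list(x)))
  invisible(x)
}
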