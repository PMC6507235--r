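#' Edge feature points of a level region
#'
#' The edge of a region is its inner boundary under 4-connectivity: every
#' region pixel with at least one of its four axial neighbors outside the
#' region (pixels beyond the image frame count as outside, so a full-frame
#' region yields its border ring). This definition is deterministic and
#' parameter-free.
#'
#' @param x logical matrix (the level's binary image), or an integer label
#'   map if `level` is given.
#' @param level optional class index selecting `x == level`.
#' @return A `trs_edge_points` object: `points` (n x 2 matrix of (row, col)),
#'   plus the originating `level`.
#' @export
detect_edges <- function(x, level = NULL) {
  if (!is.null(level)) x <- x == level
  if (!is.logical(x)) x <- x > 0
  if (!is.matrix(x)) stop("input must be a matrix", call. = FALSE)
  if (!any(x)) stop("empty level region", call. = FALSE)
  nr <- nrow(x); nc <- ncol(x)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- x
  interior <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
              pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  edge <- x & !interior
  structure(
    list(points = which(edge, arr.ind = TRUE, useNames = FALSE),
         level = level, dim = c(nr, nc)),
    class = "trs_edge_points"
  )
}

#' Count occupied boxes across a schedule of box sizes
#'
#' For each box side `delta`, the plane is tiled by a grid of side `delta`
#' anchored at the point set's bounding-box origin and the cells containing
#' at least one point are counted. Counts are averaged over `n_offsets` grid
#' phases (offsets of 0 and `delta/2` along each axis when `n_offsets = 4`)
#' and kept as reals; offset averaging damps grid-phase artifacts in the
#' log-log fit. Anchoring at the bounding box makes whole-pixel translations
#' of the point set leave the counts unchanged.
#'
#' @param points a `trs_edge_points`, or an n x 2 matrix of (row, col)
#'   coordinates.
#' @param sizes positive box sides in pixels.
#' @param n_offsets 1 (anchored grid only) or 4 (offset averaging).
#' @return A `trs_boxcount` with `box_sizes` (descending), `counts`,
#'   `log_sizes`, `log_counts`.
#' @export
box_count <- function(points, sizes, n_offsets = 4) {
  if (inherits(points, "trs_edge_points")) points <- points$points
  if (!is.matrix(points) || ncol(points) != 2L || nrow(points) == 0L) {
    stop("`points` must be a non-empty n x 2 coordinate matrix", call. = FALSE)
  }
  if (any(sizes <= 0)) stop("box sizes must be positive", call. = FALSE)
  if (!n_offsets %in% c(1L, 4L)) stop("n_offsets must be 1 or 4", call. = FALSE)
  sizes <- sort(unique(as.numeric(sizes)))
  r <- points[, 1] - min(points[, 1])
  c <- points[, 2] - min(points[, 2])
  offs <- if (n_offsets == 4L) {
    cbind(rep(c(0, 0.5), 2), rep(c(0, 0.5), each = 2))
  } else {
    matrix(0, 1, 2)
  }
  counts <- vapply(sizes, function(delta) {
    mean(apply(offs, 1, function(o) {
      ir <- floor((r + o[1] * delta) / delta)
      ic <- floor((c + o[2] * delta) / delta)
      length(unique(ir * (max(ic) + 1L) + ic))
    }))
  }, numeric(1))
  if (any(diff(counts) > 0)) {
    stop("box-count monotonicity violated: N(delta) increased with delta",
         call. = FALSE)
  }
  structure(
    list(box_sizes = rev(sizes), counts = rev(counts),
         log_sizes = log(rev(sizes)), log_counts = log(rev(counts)),
         n_points = nrow(points), n_offsets = n_offsets),
    class = "trs_boxcount"
  )
}

#' Build a box-count curve from explicit (size, count) pairs
#'
#' Useful for re-fitting a dimension from serialized results.
#'
#' @param sizes positive box sides.
#' @param counts matching occupied-box counts (>= 1).
#' @return A `trs_boxcount`.
#' @export
boxcount_curve <- function(sizes, counts) {
  if (length(sizes) != length(counts) || any(sizes <= 0) || any(counts < 1)) {
    stop("sizes and counts must match, with sizes > 0 and counts >= 1",
         call. = FALSE)
  }
  o <- order(sizes, decreasing = TRUE)
  structure(
    list(box_sizes = sizes[o], counts = counts[o],
         log_sizes = log(sizes[o]), log_counts = log(counts[o]),
         n_points = NA_integer_, n_offsets = NA_integer_),
    class = "trs_boxcount"
  )
}

#' @export
print.trs_boxcount <- function(x, ...) {
  cat(sprintf("<trs_boxcount> %d points; delta = {%s}; N = {%s}\n",
              x$n_points, paste(x$box_sizes, collapse = ", "),
              paste(signif(x$counts, 4), collapse = ", ")))
  invisible(x)
}

#' Box-counting dimension from a count curve
#'
#' Ordinary least squares of `log N(delta)` against `log(1/delta)`; the
#' slope is the box-dimension estimate (the practical surrogate for the
#' Hausdorff dimension of the point set). A constant count curve has slope 0
#' by construction and is reported with `r_squared = 1` (the constant fit is
#' exact).
#'
#' @param curve a `trs_boxcount` (needs at least 3 distinct box sizes).
#' @return A list: `slope`, `intercept`, `r_squared`.
#' @examples
#' cv <- box_count(cbind(1, 1:100), sizes = c(2, 4, 8, 16))
#' fit_dimension(cv)$slope  # ~1: points on a line
#' @export
fit_dimension <- function(curve) {
  stopifnot(inherits(curve, "trs_boxcount"))
  if (length(unique(curve$box_sizes)) < 3L) {
    stop("need at least 3 distinct box sizes", call. = FALSE)
  }
  x <- -curve$log_sizes           # log(1/delta)
  y <- curve$log_counts
  if (stats::var(x) == 0) stop("zero variance in log box sizes", call. = FALSE)
  if (stats::var(y) == 0) {
    return(list(slope = 0, intercept = mean(y), r_squared = 1))
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r_squared = 1 - ss_res / ss_tot)
}

# Dyadic box-size schedule for an ROI of the given minimal extent: powers of
# two from 2 up to max(extent/4, 16), so at least {2, 4, 8, 16} are present.
default_box_sizes <- function(extent) {
  upper <- max(16, floor(extent / 4))
  2^seq(1L, max(4L, floor(log2(upper))))
}

#' Roughness of one segmented slice
#'
#' For every nonempty intensity level of the segmentation: extract edge
#' points, box-count them on a dyadic size schedule, and fit the box
#' dimension. The slice score is the mean slope over nonempty levels.
#' Slopes are clipped to \[0, 2\] (the attainable range for planar point
#' sets) with a warning if the fit strays outside.
#'
#' @param segmentation a `trs_segmentation` from [segment_slice()].
#' @param box_sizes optional explicit box-size schedule; default is the
#'   dyadic schedule from the ROI extent.
#' @param n_offsets grid offsets passed to [box_count()].
#' @return A list: `score`, `levels` (data.frame with level, n_points,
#'   slope, r_squared), `curves` (per-level `trs_boxcount`s).
#' @export
score_slice <- function(segmentation, box_sizes = NULL, n_offsets = 4) {
  stopifnot(inherits(segmentation, "trs_segmentation"))
  lab <- segmentation$label_map
  roi <- lab > 0L
  if (!any(roi)) stop("all levels empty", call. = FALSE)
  if (is.null(box_sizes)) {
    bb <- roi_bbox(roi)
    extent <- min(bb$r[2] - bb$r[1] + 1L, bb$c[2] - bb$c[1] + 1L)
    box_sizes <- default_box_sizes(extent)
  }
  rows <- list()
  curves <- list()
  for (m in seq_len(segmentation$num_classes)) {
    if (!any(lab == m)) next
    ep <- detect_edges(lab, level = m)
    cv <- box_count(ep, box_sizes, n_offsets = n_offsets)
    ft <- fit_dimension(cv)
    slope <- ft$slope
    if (slope < 0 || slope > 2) {
      warning(sprintf("level %d slope %.3f outside [0, 2]; clipped", m, slope))
      slope <- min(2, max(0, slope))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      level = m, n_points = nrow(ep$points), slope = slope,
      r_squared = ft$r_squared)
    curves[[as.character(m)]] <- cv
  }
  if (length(rows) == 0L) stop("all levels empty", call. = FALSE)
  levels <- do.call(rbind, rows)
  list(score = mean(levels$slope), levels = levels, curves = curves)
}

#' Tumor Roughness Score of a CT stack
#'
#' The full three-stage pipeline. Per slice with a usable ROI (at least
#' `min_roi_pixels` mask pixels): stage 1 enhances the slice inside the
#' dilated ROI bounding box ([enhance_slice()]); stage 2 partitions the ROI
#' into `M` intensity levels by alpha-trimmed variance maximization
#' ([segment_slice()]); stage 3 scores each level's edge set by its
#' box-counting dimension ([score_slice()]). The combined score `R_avg` is
#' the unweighted mean of the per-slice scores. Smooth, homogeneous masses
#' score near 1 (their level boundaries are smooth curves); irregular,
#' heterogeneous masses score higher.
#'
#' @param stack a `trs_image_stack` (or single matrix).
#' @param mask a `trs_roi_mask` (or single logical matrix) aligned to the
#'   stack.
#' @param config a [trs_config()].
#' @return A `trs_result`: `R_avg`, `per_slice` (data.frame), `per_level`
#'   (data.frame), `curves`, `thresholds`, `skipped` slice indices, and the
#'   exact `config` used.
#' @examples
#' ph <- make_tumor_phantom(phantom_spec(perturb_amplitude = 0.1, seed = 3))
#' res <- tumor_roughness_score(ph$stack, ph$mask)
#' res$R_avg
#' @export
tumor_roughness_score <- function(stack, mask, config = trs_config()) {
  if (is.matrix(stack)) stack <- image_stack(stack)
  if (is.matrix(mask)) mask <- roi_mask(mask)
  stopifnot(inherits(stack, "trs_image_stack"), inherits(mask, "trs_roi_mask"))
  if (length(stack$slices) != length(mask$slices)) {
    stop("stack and mask slice counts differ", call. = FALSE)
  }
  seg_cfg <- config$segmentation
  rgh_cfg <- config$roughness
  per_slice <- list(); per_level <- list()
  curves <- list(); thresholds <- list()
  skipped <- integer(0)
  for (s in seq_along(stack$slices)) {
    m <- mask$slices[[s]]
    if (sum(m) < rgh_cfg$min_roi_pixels) {
      skipped <- c(skipped, s)
      next
    }
    img <- stack$slices[[s]]
    if (isTRUE(config$enhancement$enabled)) {
      img <- enhance_slice(img, config$enhancement$config, mask = m)
    }
    seg <- tryCatch(
      segment_slice(img, m, M = seg_cfg$levels, alpha = seg_cfg$alpha,
                    bins = seg_cfg$bins),
      trs_degenerate_roi = function(e) NULL)
    if (is.null(seg)) {
      warning(sprintf("slice %d: degenerate ROI (too few distinct gray values); skipped", s))
      skipped <- c(skipped, s)
      next
    }
    sc <- score_slice(seg, box_sizes = rgh_cfg$box_sizes,
                      n_offsets = rgh_cfg$n_offsets)
    per_slice[[length(per_slice) + 1L]] <- data.frame(
      slice = s, score = sc$score, n_roi = sum(m),
      n_levels = nrow(sc$levels))
    lv <- sc$levels
    lv$slice <- s
    per_level[[length(per_level) + 1L]] <- lv[, c("slice", "level",
                                                  "n_points", "slope",
                                                  "r_squared")]
    curves[[as.character(s)]] <- sc$curves
    thresholds[[as.character(s)]] <- seg$thresholds
  }
  if (length(per_slice) == 0L) {
    stop("no slice with a usable ROI", call. = FALSE)
  }
  per_slice <- do.call(rbind, per_slice)
  per_level <- do.call(rbind, per_level)
  structure(
    list(R_avg = mean(per_slice$score),
         per_slice = per_slice, per_level = per_level,
         thresholds = thresholds, curves = curves, skipped = skipped,
         config = config,
         version = as.character(utils::packageVersion("trscore"))),
    class = "trs_result"
  )
}

#' @export
print.trs_result <- function(x, ...) {
  cat(sprintf("<trs_result> R_avg = %.4f over %d slice(s)%s\n",
              x$R_avg, nrow(x$per_slice),
              if (length(x$skipped)) sprintf(" (%d skipped)", length(x$skipped))
              else ""))
  print(x$per_slice, row.names = FALSE)
  invisible(x)
}
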