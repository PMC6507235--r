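#' Enhancement stage configuration
#'
#' Stage 1 of the roughness pipeline improves contrast and edge content
#' before thresholding: an edge-preserving guided smooth, unsharp-style edge
#' enhancement, and a convex-combination fusion of the original slice with
#' its enhanced version.
#'
#' @param guided_radius box-window radius of the guided filter, pixels.
#' @param guided_epsilon guided-filter regularizer (squared gray units);
#'   larger values smooth more aggressively across weak edges.
#' @param edge_gain unsharp amount (>= 0); 0 disables sharpening.
#' @param fusion_weights non-negative pair `(original, enhanced)` summing to
#'   1 used by [fuse_slices()].
#' @param roi_dilation pixels by which the ROI bounding box is dilated before
#'   enhancement is applied inside it (see [enhance_slice()]).
#' @return An `trs_enhancement_config` list.
#' @export
enhancement_config <- function(guided_radius = 4, guided_epsilon = 1e-3,
                               edge_gain = 1.0, fusion_weights = c(0.5, 0.5),
                               roi_dilation = 8) {
  if (guided_radius < 1) stop("guided_radius must be >= 1", call. = FALSE)
  if (guided_epsilon <= 0) stop("guided_epsilon must be positive", call. = FALSE)
  if (edge_gain < 0) stop("edge_gain must be >= 0", call. = FALSE)
  if (length(fusion_weights) != 2L || any(fusion_weights < 0) ||
      abs(sum(fusion_weights) - 1) > 1e-9) {
    stop("fusion_weights must be two non-negative values summing to 1",
         call. = FALSE)
  }
  structure(
    list(guided_radius = as.integer(guided_radius),
         guided_epsilon = guided_epsilon, edge_gain = edge_gain,
         fusion_weights = as.numeric(fusion_weights),
         roi_dilation = as.integer(roi_dilation)),
    class = "trs_enhancement_config"
  )
}

# Local box mean with edge-clipped windows, via integral images. Windows are
# (2r+1)^2 clipped at the image border; each mean divides by the number of
# pixels actually inside.
box_mean <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- matrix(apply(m, 2, cumsum), nr, nc)          # down columns
  cs <- t(matrix(apply(cs, 1, cumsum), nc, nr))      # then across rows
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- cs
  i1 <- pmax(seq_len(nr) - r, 1L); i2 <- pmin(seq_len(nr) + r, nr)
  j1 <- pmax(seq_len(nc) - r, 1L); j2 <- pmin(seq_len(nc) + r, nc)
  sums <- S[i2 + 1L, j2 + 1L, drop = FALSE] - S[i1, j2 + 1L, drop = FALSE] -
          S[i2 + 1L, j1, drop = FALSE] + S[i1, j1, drop = FALSE]
  counts <- outer(i2 - i1 + 1L, j2 - j1 + 1L)
  sums / counts
}

#' Edge-preserving smoothing with a guided filter
#'
#' Self-guided filter: within each window the output is modelled as a local
#' linear transform `a * I + b` of the input, with `a = var / (var + eps)`,
#' so flat regions (variance << eps) are replaced by their local mean while
#' strong edges (variance >> eps) pass through. Output is clipped to the
#' input's range.
#'
#' @param image numeric matrix (2-D grayscale slice), finite values.
#' @param config an [enhancement_config()].
#' @return Smoothed matrix, same dimensions.
#' @export
guided_smooth <- function(image, config = enhancement_config()) {
  stopifnot_matrix(image)
  r <- config$guided_radius
  eps <- config$guided_epsilon
  mean_i <- box_mean(image, r)
  var_i <- pmax(box_mean(image * image, r) - mean_i^2, 0)
  a <- var_i / (var_i + eps)
  b <- (1 - a) * mean_i
  out <- box_mean(a, r) * image + box_mean(b, r)
  clip_range(out, min(image), max(image))
}

#' Unsharp-style edge enhancement
#'
#' Adds `edge_gain` times the high-pass residual `image - smoothed(image)`
#' back to the image, then clips to \[0, 1\].
#'
#' @inheritParams guided_smooth
#' @return Sharpened matrix.
#' @export
edge_enhance <- function(image, config = enhancement_config()) {
  stopifnot_matrix(image)
  if (config$edge_gain == 0) return(image)
  sm <- guided_smooth(image, config)
  clip01(image + config$edge_gain * (image - sm))
}

#' Fuse two slices by convex combination
#'
#' Pixelwise `w1 * a + w2 * b` followed by renormalization of the result's
#' range to \[0, 1\] (a constant fused image is returned unchanged, clipped).
#'
#' @param image_a,image_b equal-shape numeric matrices.
#' @inheritParams guided_smooth
#' @return Fused matrix with values in \[0, 1\].
#' @export
fuse_slices <- function(image_a, image_b, config = enhancement_config()) {
  stopifnot_matrix(image_a, "image_a")
  stopifnot_matrix(image_b, "image_b")
  if (!identical(dim(image_a), dim(image_b))) {
    stop("image_a and image_b must have the same shape", call. = FALSE)
  }
  w <- config$fusion_weights
  f <- w[1] * image_a + w[2] * image_b
  rng <- range(f)
  if (rng[2] - rng[1] > 0) (f - rng[1]) / (rng[2] - rng[1]) else clip01(f)
}

# Bounding box of TRUE pixels, dilated by `pad` and clipped to the image.
roi_bbox <- function(mask, pad = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty ROI", call. = FALSE)
  list(r = c(max(1L, min(idx[, 1]) - pad), min(nrow(mask), max(idx[, 1]) + pad)),
       c = c(max(1L, min(idx[, 2]) - pad), min(ncol(mask), max(idx[, 2]) + pad)))
}

#' Enhance one slice (stage 1 of the pipeline)
#'
#' Composition `guided_smooth` then `edge_enhance`, fused with the original
#' slice using `fusion_weights`. When a mask is supplied, enhancement runs
#' only inside the mask's bounding box dilated by `roi_dilation` pixels
#' (background far from the tumor is left untouched); the fusion
#' renormalization then uses that crop's range.
#'
#' @inheritParams guided_smooth
#' @param mask optional logical matrix; restricts enhancement to the dilated
#'   ROI bounding box.
#' @return Enhanced slice, values in \[0, 1\].
#' @export
enhance_slice <- function(image, config = enhancement_config(), mask = NULL) {
  stopifnot_matrix(image)
  if (!is.null(mask)) {
    bb <- roi_bbox(mask, config$roi_dilation)
    crop <- image[bb$r[1]:bb$r[2], bb$c[1]:bb$c[2], drop = FALSE]
    out <- image
    out[bb$r[1]:bb$r[2], bb$c[1]:bb$c[2]] <-
      enhance_slice(crop, config, mask = NULL)
    return(out)
  }
  enhanced <- edge_enhance(guided_smooth(image, config), config)
  fuse_slices(image, enhanced, config)
}
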