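#' Image stack and ROI mask containers
#'
#' An `trs_image_stack` is an ordered list of 2-D grayscale slices (numeric
#' matrices with values in \[0, 1\]) plus pixel/slice spacing in millimetres.
#' An `trs_roi_mask` holds per-slice logical matrices aligned to a stack:
#' `TRUE` marks tumor.
#'
#' @param slices list of numeric matrices (gray values in \[0, 1\]), all the
#'   same dimensions.
#' @param pixel_spacing numeric length-2, (row mm, col mm); must be positive.
#' @param slice_spacing positive scalar, mm between slices.
#' @param source optional list of provenance metadata (file paths etc.).
#' @return An object of class `trs_image_stack`.
#' @export
image_stack <- function(slices, pixel_spacing = c(1, 1), slice_spacing = 1,
                        source = list()) {
  if (is.matrix(slices)) slices <- list(slices)
  if (!is.list(slices) || length(slices) == 0L) {
    stop("`slices` must be a non-empty list of matrices", call. = FALSE)
  }
  for (s in slices) stopifnot_matrix(s, "slice")
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all slices must share the same dimensions", call. = FALSE)
  }
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0) ||
      length(slice_spacing) != 1L || slice_spacing <= 0) {
    stop("spacings must be positive", call. = FALSE)
  }
  structure(
    list(slices = slices,
         pixel_spacing = as.numeric(pixel_spacing),
         slice_spacing = as.numeric(slice_spacing),
         source = source),
    class = "trs_image_stack"
  )
}

#' @param mask_slices list of logical (or 0/1 numeric) matrices; values > 0
#'   are foreground.
#' @param stack optional `trs_image_stack` to validate geometry against.
#' @rdname image_stack
#' @export
roi_mask <- function(mask_slices, stack = NULL) {
  if (is.matrix(mask_slices)) mask_slices <- list(mask_slices)
  if (!is.list(mask_slices) || length(mask_slices) == 0L) {
    stop("`mask_slices` must be a non-empty list of matrices", call. = FALSE)
  }
  mask_slices <- lapply(mask_slices, function(m) {
    if (!is.matrix(m)) stop("mask slices must be matrices", call. = FALSE)
    m <- m > 0
    storage.mode(m) <- "logical"
    m
  })
  if (!is.null(stack)) {
    if (length(mask_slices) != length(stack$slices)) {
      stop("mask and stack slice counts differ", call. = FALSE)
    }
    for (i in seq_along(mask_slices)) {
      if (!identical(dim(mask_slices[[i]]), dim(stack$slices[[i]]))) {
        stop(sprintf("mask slice %d geometry does not match the stack", i),
             call. = FALSE)
      }
    }
  }
  if (sum(vapply(mask_slices, sum, numeric(1))) == 0) {
    stop("mask has no foreground pixel on any slice", call. = FALSE)
  }
  structure(list(slices = mask_slices), class = "trs_roi_mask")
}

#' @export
print.trs_image_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<trs_image_stack> %d slice(s) of %dx%d, spacing (%g, %g) mm, slice gap %g mm\n",
              length(x$slices), d[1], d[2],
              x$pixel_spacing[1], x$pixel_spacing[2], x$slice_spacing))
  invisible(x)
}

#' @export
print.trs_roi_mask <- function(x, ...) {
  n <- vapply(x$slices, sum, numeric(1))
  cat(sprintf("<trs_roi_mask> %d slice(s); foreground pixels: %s\n",
              length(x$slices), paste(n, collapse = ", ")))
  invisible(x)
}
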