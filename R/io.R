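# Window/level mapping: HU (or raw) values to [0, 1]; out-of-window clipped.
apply_window <- function(v, center, width) {
  clip01((v - (center - width / 2)) / width)
}

read_gray_image <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- switch(ext,
    png = png::readPNG(f),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(f)
    },
    stop(sprintf("unsupported image format: %s", f), call. = FALSE))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)  # to grayscale
  img
}

#' Read a CT stack from disk
#'
#' Accepts a NIfTI volume (`.nii` / `.nii.gz`) or a directory of 2-D
#' grayscale PNG/TIFF slices (sorted by filename). NIfTI voxel values are
#' mapped to \[0, 1\] by window/level (soft-tissue default 40/400 when the
#' data look like HU); data already in \[0, 1\] are taken as-is when no
#' window is requested. Missing spacing metadata falls back to 1 mm with a
#' warning.
#'
#' @param path NIfTI file or slice directory.
#' @param window_center,window_width window/level for HU conversion;
#'   `NULL` auto-selects (identity for \[0, 1\] data, 40/400 otherwise).
#' @return A [image_stack()].
#' @export
read_stack <- function(path, window_center = NULL, window_width = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("no PNG/TIFF slices found in ", path, call. = FALSE)
    slices <- lapply(files, read_gray_image)
    if (!is.null(window_center)) {
      slices <- lapply(slices, apply_window, center = window_center,
                       width = window_width)
    }
    warning("no spacing metadata in image directory; assuming 1 mm")
    return(image_stack(slices, source = list(path = path, files = basename(files))))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L) stop("expected a 2-D or 3-D NIfTI volume", call. = FALSE)
    if (is.null(window_center)) {
      rng <- range(arr)
      if (rng[1] >= -1e-9 && rng[2] <= 1 + 1e-9) {
        window_center <- 0.5; window_width <- 1
      } else {
        window_center <- 40; window_width <- 400
        message("HU-valued volume: applying soft-tissue window (40, 400)")
      }
    }
    pd <- tryCatch(RNifti::pixdim(vol), error = function(e) NULL)
    if (is.null(pd) || length(pd) < 3L || any(pd[1:3] <= 0)) {
      warning("missing or invalid voxel spacing; assuming 1 mm")
      pd <- c(1, 1, 1)
    }
    slices <- lapply(seq_len(dim(arr)[3]), function(k) {
      apply_window(arr[, , k], window_center, window_width)
    })
    return(image_stack(slices, pixel_spacing = pd[1:2], slice_spacing = pd[3],
                       source = list(path = path,
                                     window = c(window_center, window_width))))
  }
  stop("`path` must be a NIfTI file or a directory of PNG/TIFF slices",
       call. = FALSE)
}

#' Read a per-slice tumor mask aligned to a stack
#'
#' Same formats as [read_stack()]; values > 0 are foreground. Geometry is
#' validated against the stack and per-slice foreground counts are reported.
#'
#' @param path NIfTI file or slice directory.
#' @param stack the `trs_image_stack` the mask belongs to.
#' @return A [roi_mask()].
#' @export
read_mask <- function(path, stack) {
  stopifnot(inherits(stack, "trs_image_stack"))
  raw <- suppressWarnings(suppressMessages(
    read_stack(path, window_center = 0.5, window_width = 1)))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    # re-read without windowing: masks may use any positive label value
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    raw$slices <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
  }
  mask <- roi_mask(lapply(raw$slices, function(s) s > 0), stack)
  counts <- vapply(mask$slices, sum, numeric(1))
  message("mask foreground pixels per slice: ", paste(counts, collapse = ", "))
  mask
}

#' Write a stack (or mask) to disk
#'
#' @param stack a `trs_image_stack` or `trs_roi_mask`.
#' @param path output NIfTI filename (`.nii` / `.nii.gz`) or a directory
#'   (PNG per slice).
#' @param format `"nifti"` or `"png"`; inferred from `path` when missing.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, format = NULL) {
  slices <- if (inherits(stack, "trs_roi_mask")) {
    lapply(stack$slices, function(m) m * 1)
  } else {
    stack$slices
  }
  if (is.null(format)) {
    format <- if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti" else "png"
  }
  if (format == "nifti") {
    arr <- array(0, dim = c(dim(slices[[1]]), length(slices)))
    for (k in seq_along(slices)) arr[, , k] <- slices[[k]]
    sp <- if (inherits(stack, "trs_image_stack")) {
      c(stack$pixel_spacing, stack$slice_spacing)
    } else {
      c(1, 1, 1)
    }
    img <- RNifti::asNifti(arr, pixdim = sp)
    RNifti::writeNifti(img, path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_along(slices)) {
      png::writePNG(clip01(slices[[k]]),
                    file.path(path, sprintf("slice_%03d.png", k)))
    }
  }
  invisible(path)
}

#' Serialize a roughness result to JSON
#'
#' Writes `R_avg`, per-slice and per-level scores, thresholds, the full
#' box-count curves, the exact configuration and the package version — the
#' result is reproducible from the inputs plus this embedded config alone.
#'
#' @param result a `trs_result`.
#' @param path output `.json` filename.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "trs_result"))
  curves <- lapply(result$curves, function(slice_curves) {
    lapply(slice_curves, function(cv) {
      list(box_sizes = cv$box_sizes, counts = cv$counts,
           n_points = cv$n_points)
    })
  })
  out <- list(
    R_avg = result$R_avg,
    per_slice = result$per_slice,
    per_level = result$per_level,
    thresholds = result$thresholds,
    curves = curves,
    skipped = result$skipped,
    config = trs_config_to_list(result$config),
    version = result$version
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Append one subject's score to a cohort CSV
#'
#' One row per subject: `subject_id`, `r_avg`, `n_slices`. Creates the file
#' (with header) when absent; this CSV is the input joined with
#' demographics for the cohort-statistics layer.
#'
#' @param result a `trs_result`.
#' @param subject_id subject identifier.
#' @param path CSV filename.
#' @return `path`, invisibly.
#' @export
write_cohort_row <- function(result, subject_id, path) {
  stopifnot(inherits(result, "trs_result"))
  row <- data.frame(subject_id = subject_id, r_avg = result$R_avg,
                    n_slices = nrow(result$per_slice))
  utils::write.table(row, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}
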