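#' Specify a synthetic tumor phantom
#'
#' A phantom is a thin stack of grayscale slices containing one bright,
#' roughly circular "tumor" on a darker background. The boundary radius is
#' \deqn{r(\theta) = R \, (1 + a \, p(\theta)),}
#' where \eqn{p(\theta)} is a random-phase sum of angular harmonics
#' normalized to peak amplitude 1, so `perturb_amplitude` \eqn{a} is exactly
#' the maximal fractional radial deviation. `a = 0` gives a perfect disk;
#' increasing `a` gives an ordered family of ever-rougher boundaries, which
#' is what makes the phantom a ground-truth input for roughness scoring.
#'
#' @param image_size pixels per side (>= 64).
#' @param base_radius mean boundary radius in pixels.
#' @param perturb_amplitude maximal fractional radial perturbation, in
#'   \[0, 1): 0 is a perfect disk.
#' @param perturb_harmonics number of angular frequency components (the
#'   harmonics used are k = 3, 4, ..., 2 + `perturb_harmonics`; k <= 2 would
#'   only translate/elongate the shape rather than roughen it).
#' @param noise_sigma standard deviation of additive Gaussian intensity
#'   noise, in gray units on the \[0, 1\] scale.
#' @param foreground_level,background_level gray values in \[0, 1\].
#' @param shading radial intensity drop (gray units) from the tumor center
#'   to its boundary, emulating the contrast washout of enhancing renal
#'   masses: inside the region the intensity is
#'   `foreground_level - shading * (d / r(theta))^2`. This gives the ROI a
#'   smooth internal gradient whose intensity level sets are concentric
#'   scaled copies of the boundary — the structure the multilevel stage is
#'   meant to latch onto. `shading = 0` gives a flat (noise-only) interior.
#' @param n_slices slices in the stack; each slice draws fresh harmonic
#'   phases, mimicking successive cuts through one lesion.
#' @param seed integer RNG seed; the phantom is a pure function of
#'   (spec, seed).
#' @return A `trs_phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 192, base_radius = 60,
                         perturb_amplitude = 0, perturb_harmonics = 6,
                         noise_sigma = 0.002, foreground_level = 0.7,
                         background_level = 0.2, shading = 0.15,
                         n_slices = 3, seed = 1) {
  if (image_size < 64) stop("image_size must be >= 64", call. = FALSE)
  if (perturb_amplitude < 0 || perturb_amplitude >= 1) {
    stop("perturb_amplitude must be in [0, 1): at 1 the boundary would reach the center",
         call. = FALSE)
  }
  if (base_radius <= 0) stop("base_radius must be positive", call. = FALSE)
  max_r <- base_radius * (1 + perturb_amplitude)
  if (max_r >= image_size / 2 - 2) {
    stop("perturbed boundary would exceed the image frame", call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (shading < 0) stop("shading must be >= 0", call. = FALSE)
  if (perturb_harmonics < 1) stop("perturb_harmonics must be >= 1", call. = FALSE)
  structure(
    list(image_size = as.integer(image_size), base_radius = base_radius,
         perturb_amplitude = perturb_amplitude,
         perturb_harmonics = as.integer(perturb_harmonics),
         noise_sigma = noise_sigma, foreground_level = foreground_level,
         background_level = background_level, shading = shading,
         n_slices = as.integer(n_slices), seed = as.integer(seed)),
    class = "trs_phantom_spec"
  )
}

#' Generate a tumor phantom stack and its ground-truth mask
#'
#' Rasterizes the star-shaped region \eqn{d \le r(\theta)} on each slice,
#' paints foreground/background gray levels, then adds intensity noise
#' (after shape rasterization, so the mask is exact).
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `stack` (`trs_image_stack`) and `mask`
#'   (`trs_roi_mask`).
#' @examples
#' ph <- make_tumor_phantom(phantom_spec(perturb_amplitude = 0.2, seed = 7))
#' ph$stack
#' @export
make_tumor_phantom <- function(spec) {
  stopifnot(inherits(spec, "trs_phantom_spec"))
  n <- spec$image_size
  ctr <- (n + 1) / 2
  ix <- matrix(seq_len(n), n, n)          # row coordinate
  jx <- matrix(seq_len(n), n, n, byrow = TRUE)
  dy <- ix - ctr
  dx <- jx - ctr
  d <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  harmonics <- 2 + seq_len(spec$perturb_harmonics)

  with_seed(spec$seed, {
    slices <- vector("list", spec$n_slices)
    masks <- vector("list", spec$n_slices)
    for (s in seq_len(spec$n_slices)) {
      if (spec$perturb_amplitude > 0) {
        w <- stats::runif(length(harmonics), 0.2, 1)
        phi <- stats::runif(length(harmonics), 0, 2 * pi)
        # normalize the harmonic mix to peak 1 on a fine angular grid
        grid <- seq(0, 2 * pi, length.out = 2048)
        pg <- colSums(w * sin(outer(harmonics, grid) + phi))
        w <- w / max(abs(pg))
        p <- matrix(0, n, n)
        for (k in seq_along(harmonics)) {
          p <- p + w[k] * sin(harmonics[k] * theta + phi[k])
        }
        r <- spec$base_radius * (1 + spec$perturb_amplitude * p)
      } else {
        # burn the same RNG draws so amplitude families share a seed stream
        stats::runif(2 * length(harmonics))
        r <- spec$base_radius
      }
      m <- d <= r
      img <- matrix(spec$background_level, n, n)
      u2 <- (d[m] / if (length(r) > 1L) r[m] else r)^2   # (d / r(theta))^2
      img[m] <- spec$foreground_level - spec$shading * u2
      if (spec$noise_sigma > 0) {
        img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sigma), n, n)
      }
      slices[[s]] <- clip01(img)
      masks[[s]] <- m
    }
    stack <- image_stack(slices, source = list(phantom = unclass(spec)))
    list(stack = stack, mask = roi_mask(masks, stack))
  })
}

#' Specify a classical fractal fixture
#'
#' Fixtures with analytically known box-counting dimension, used to validate
#' the dimension estimator: a straight line (dimension 1), a single point
#' (0), the Koch curve (log 4 / log 3), the Sierpinski triangle
#' (log 3 / log 2), and a filled square (2).
#'
#' @param kind one of `"line_segment"`, `"single_point"`, `"koch_curve"`,
#'   `"sierpinski_triangle"`, `"filled_square"`.
#' @param iterations recursion depth (ignored for point/line/square); capped
#'   so the finest feature is at least one pixel.
#' @param image_size pixels per side.
#' @return A `trs_fractal_spec` with a `theoretical_dimension` field.
#' @export
fractal_spec <- function(kind = c("line_segment", "single_point", "koch_curve",
                                  "sierpinski_triangle", "filled_square"),
                         iterations = 0, image_size = 512) {
  kind <- match.arg(kind)
  if (iterations < 0) stop("iterations must be >= 0", call. = FALSE)
  span <- 0.9 * image_size
  max_iter <- switch(kind,
    koch_curve = floor(log(span) / log(3)),
    sierpinski_triangle = floor(log(span) / log(2)),
    Inf)
  if (iterations > max_iter) {
    stop(sprintf("iterations = %d too deep for image_size = %d (finest feature < 1 px)",
                 iterations, image_size), call. = FALSE)
  }
  dim_theory <- switch(kind,
    line_segment = 1.0,
    single_point = 0.0,
    koch_curve = log(4) / log(3),
    sierpinski_triangle = log(3) / log(2),
    filled_square = 2.0)
  structure(
    list(kind = kind, iterations = as.integer(iterations),
         image_size = as.integer(image_size),
         theoretical_dimension = dim_theory),
    class = "trs_fractal_spec"
  )
}

# Rasterize a polyline given as an n x 2 matrix of (x, y): sample each
# segment at sub-half-pixel steps and round to pixel centers.
rasterize_polyline <- function(pts, image_size) {
  img <- matrix(FALSE, image_size, image_size)
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len / 0.4) + 1L))
    xs <- round(a[1] + t * (b[1] - a[1]))
    ys <- round(a[2] + t * (b[2] - a[2]))
    keep <- xs >= 1 & xs <= image_size & ys >= 1 & ys <= image_size
    img[cbind(ys[keep], xs[keep])] <- TRUE
  }
  img
}

koch_vertices <- function(p0, p1, iterations) {
  pts <- rbind(p0, p1)
  for (it in seq_len(iterations)) {
    out <- matrix(0, nrow = 4 * (nrow(pts) - 1) + 1, ncol = 2)
    n_out <- 0L
    for (i in seq_len(nrow(pts) - 1)) {
      a <- pts[i, ]; b <- pts[i + 1, ]
      v <- (b - a) / 3
      # outward peak: rotate v by -60 degrees (bump rises in image y)
      peak <- a + v + c(v[1] * 0.5 + v[2] * sqrt(3) / 2,
                        -v[1] * sqrt(3) / 2 + v[2] * 0.5)
      seg <- rbind(a, a + v, peak, a + 2 * v)
      out[n_out + 1:4, ] <- seg
      n_out <- n_out + 4L
    }
    out[n_out + 1L, ] <- pts[nrow(pts), ]
    pts <- out
  }
  pts
}

#' Rasterize a fractal fixture as a binary point-set image
#'
#' @param spec a [fractal_spec()].
#' @return A logical matrix; attribute `theoretical_dimension` carries the
#'   analytic box dimension.
#' @examples
#' k <- make_fractal_points(fractal_spec("koch_curve", iterations = 4))
#' sum(k)
#' @export
make_fractal_points <- function(spec) {
  stopifnot(inherits(spec, "trs_fractal_spec"))
  n <- spec$image_size
  ctr <- (n + 1) / 2
  span <- 0.9 * n
  img <- switch(spec$kind,
    single_point = {
      m <- matrix(FALSE, n, n)
      m[round(ctr), round(ctr)] <- TRUE
      m
    },
    line_segment = ,
    koch_curve = {
      iters <- if (spec$kind == "line_segment") 0L else spec$iterations
      x0 <- ctr - span / 2
      x1 <- ctr + span / 2
      # leave head-room for the bumps (height span * sqrt(3)/6)
      y <- ctr + span * sqrt(3) / 12
      pts <- koch_vertices(c(x0, y), c(x1, y), iters)
      rasterize_polyline(pts, n)
    },
    sierpinski_triangle = {
      side <- span
      h <- side * sqrt(3) / 2
      base_y <- ctr + h / 2
      tri0 <- rbind(c(ctr - side / 2, base_y),
                    c(ctr + side / 2, base_y),
                    c(ctr, base_y - h))
      tris <- list(tri0)
      for (it in seq_len(spec$iterations)) {
        tris <- unlist(lapply(tris, function(tr) {
          m01 <- (tr[1, ] + tr[2, ]) / 2
          m02 <- (tr[1, ] + tr[3, ]) / 2
          m12 <- (tr[2, ] + tr[3, ]) / 2
          list(rbind(tr[1, ], m01, m02),
               rbind(m01, tr[2, ], m12),
               rbind(m02, m12, tr[3, ]))
        }), recursive = FALSE)
      }
      m <- matrix(FALSE, n, n)
      for (tr in tris) m <- m | rasterize_triangle(tr, n)
      m
    },
    filled_square = {
      side <- 0.8 * n
      lo <- max(1L, round(ctr - side / 2))
      hi <- min(n, round(ctr + side / 2))
      m <- matrix(FALSE, n, n)
      m[lo:hi, lo:hi] <- TRUE
      m
    })
  attr(img, "theoretical_dimension") <- spec$theoretical_dimension
  img
}

# Fill a triangle (3 x 2 matrix of (x, y)) by barycentric sign tests over its
# bounding box; half-pixel slack keeps adjacent subdivision triangles joined.
rasterize_triangle <- function(tr, image_size) {
  img <- matrix(FALSE, image_size, image_size)
  xs <- max(1L, floor(min(tr[, 1]))):min(image_size, ceiling(max(tr[, 1])))
  ys <- max(1L, floor(min(tr[, 2]))):min(image_size, ceiling(max(tr[, 2])))
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  sign_edge <- function(a, b) {
    (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
  }
  d1 <- sign_edge(tr[1, ], tr[2, ])
  d2 <- sign_edge(tr[2, ], tr[3, ])
  d3 <- sign_edge(tr[3, ], tr[1, ])
  eps <- 0.5 * max(abs(tr[2, ] - tr[1, ]), abs(tr[3, ] - tr[1, ]))
  inside <- (d1 >= -eps & d2 >= -eps & d3 >= -eps) |
            (d1 <= eps & d2 <= eps & d3 <= eps)
  img[cbind(py[inside], px[inside])] <- TRUE
  img
}

#' Simulate a renal-mass cohort with group-structured roughness scores
#'
#' Draws per-subject Tumor Roughness Scores from Normal(group mean,
#' `group_sd`) and a tumor size correlated with TRS at `size_cor` (on the
#' log-size scale, keeping sizes positive), plus age, BMI and demographic
#' flags. Used to calibrate the cohort-statistics layer.
#'
#' @param n_per_group scalar or per-group vector of group sizes (>= 1 each,
#'   at least one group with >= 2).
#' @param group_means numeric vector of group mean TRS values; one group per
#'   entry, labelled with the renal-mass subtypes in ascending-aggressiveness
#'   order (benign_cyst, oncocytoma, chromophobe, clear_cell, papillary) or
#'   `group1..k` beyond five groups.
#' @param group_sd common within-group standard deviation (> 0).
#' @param seed integer RNG seed.
#' @param size_cor correlation between TRS (standardized within group) and
#'   log tumor size.
#' @return A data.frame with columns `subject_id`, `subtype`, `trs`,
#'   `tumor_size`, `age`, `bmi`, `white`, `male`.
#' @examples
#' coh <- make_synthetic_cohort(10, c(1.18, 1.16, 1.27, 1.52, 1.56),
#'                              group_sd = 0.08, seed = 1)
#' aggregate(trs ~ subtype, coh, mean)
#' @export
make_synthetic_cohort <- function(n_per_group, group_means, group_sd, seed,
                                  size_cor = 0.5) {
  k <- length(group_means)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, k)
  if (length(n_per_group) != k) {
    stop("`n_per_group` must be scalar or one entry per group", call. = FALSE)
  }
  if (any(n_per_group < 1)) stop("group sizes must be positive", call. = FALSE)
  if (max(n_per_group) < 2) stop("at least one group needs >= 2 subjects", call. = FALSE)
  if (group_sd <= 0) stop("group_sd must be positive", call. = FALSE)
  if (abs(size_cor) > 1) stop("size_cor must be in [-1, 1]", call. = FALSE)

  subtype_levels <- c("benign_cyst", "oncocytoma", "chromophobe",
                      "clear_cell", "papillary")
  labels <- if (k <= 5) subtype_levels[seq_len(k)] else paste0("group", seq_len(k))

  with_seed(seed, {
    n_tot <- sum(n_per_group)
    grp <- rep(seq_len(k), times = n_per_group)
    z1 <- stats::rnorm(n_tot)
    z2 <- stats::rnorm(n_tot)
    trs <- group_means[grp] + group_sd * z1
    log_size <- log(2.5) + 0.4 * (size_cor * z1 + sqrt(1 - size_cor^2) * z2)
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n_tot)),
      subtype = factor(labels[grp], levels = labels),
      trs = trs,
      tumor_size = exp(log_size),
      age = round(stats::rnorm(n_tot, 56, 9)),
      bmi = round(stats::rnorm(n_tot, 30, 3.5), 1),
      white = stats::runif(n_tot) < 0.59,
      male = stats::runif(n_tot) < 0.93,
      stringsAsFactors = FALSE
    )
  })
}
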