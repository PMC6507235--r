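#' Alpha-trimmed mean and variance of a sample
#'
#' Discards `floor(alpha * n)` observations from each tail of the sorted
#' sample and returns the mean and (sample) variance of the central order
#' statistics. Trimming makes the moments robust to impulse (salt-and-
#' pepper) outliers, which is the reason the thresholding stage uses trimmed
#' class statistics.
#'
#' @param values numeric vector, non-empty.
#' @param alpha trim fraction in \[0, 0.5); `alpha = 0` gives the ordinary
#'   mean and variance.
#' @return A list with `trimmed_mean` and `trimmed_variance` (0 when a
#'   single value remains).
#' @examples
#' alpha_trimmed_stats(c(1, 2, 3, 4, 100), 0.2)  # mean of 2,3,4
#' @export
alpha_trimmed_stats <- function(values, alpha) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 0.5) {
    stop("alpha must be in [0, 0.5)", call. = FALSE)
  }
  n <- length(values)
  k <- floor(alpha * n)
  if (n - 2 * k < 1L) stop("trimming leaves no observations", call. = FALSE)
  kept <- sort(values)[(k + 1L):(n - k)]
  list(trimmed_mean = mean(kept),
       trimmed_variance = if (length(kept) > 1L) stats::var(kept) else 0)
}

#' Intensity histogram of ROI pixels
#'
#' Uniform binning over `range`; probabilities sum to 1 and the total mean
#' is the probability-weighted mean of bin centers. `histogram_from_probs()`
#' builds a histogram directly from (value, probability) pairs, which is
#' convenient for exact hand-computed cases.
#'
#' @param values numeric vector of gray values.
#' @param bins number of uniform bins (default 256).
#' @param range length-2 numeric; defaults to `range(values)`.
#' @return A `trs_histogram` with fields `mids`, `counts`, `p`, `bin_edges`,
#'   `mu_T`, `n`.
#' @export
intensity_histogram <- function(values, bins = 256, range = NULL) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (is.null(range)) range <- base::range(values)
  if (diff(range) <= 0) stop("degenerate intensity range", call. = FALSE)
  edges <- seq(range[1], range[2], length.out = bins + 1L)
  b <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(b, nbins = bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(bins + 1L)]) / 2
  new_histogram(mids, p, counts, edges)
}

#' @param mids ascending representative gray values.
#' @param probs matching probabilities (normalized to sum 1).
#' @rdname intensity_histogram
#' @export
histogram_from_probs <- function(mids, probs) {
  if (length(mids) != length(probs) || length(mids) < 1L) {
    stop("mids and probs must be matching non-empty vectors", call. = FALSE)
  }
  if (is.unsorted(mids, strictly = TRUE)) {
    stop("mids must be strictly ascending", call. = FALSE)
  }
  if (any(probs < 0) || sum(probs) <= 0) {
    stop("probs must be non-negative with positive sum", call. = FALSE)
  }
  p <- probs / sum(probs)
  inner <- (mids[-1] + mids[-length(mids)]) / 2
  gap <- if (length(mids) > 1L) min(diff(mids)) / 2 else 0.5
  edges <- c(mids[1] - gap, inner, mids[length(mids)] + gap)
  new_histogram(mids, p, probs, edges)
}

new_histogram <- function(mids, p, counts, edges) {
  structure(
    list(mids = mids, p = p, counts = counts, bin_edges = edges,
         mu_T = sum(p * mids), n = length(mids)),
    class = "trs_histogram"
  )
}

#' @export
print.trs_histogram <- function(x, ...) {
  cat(sprintf("<trs_histogram> %d bins on [%g, %g], mean %.4g\n",
              x$n, x$bin_edges[1], x$bin_edges[x$n + 1L], x$mu_T))
  invisible(x)
}

#' Globally alpha-trim a histogram
#'
#' Removes an exact `alpha` fraction of the total probability mass from each
#' tail of the histogram (fractionally within the boundary bins) and
#' renormalizes. This is how the thresholding stage applies alpha-trimming:
#' the image's own trimmed distribution is thresholded, so impulse outliers
#' (salt-and-pepper spikes carrying less than `alpha` mass per tail) are
#' removed before any class statistic is computed. On the trimmed
#' distribution, maximizing between-class variance and minimizing the pooled
#' within-class variance are exactly equivalent (their sum is the fixed
#' total trimmed variance).
#'
#' @param hist a `trs_histogram`.
#' @param alpha trim fraction in \[0, 0.5); 0 returns the histogram
#'   unchanged.
#' @return A `trs_histogram` with the trimmed, renormalized probabilities.
#' @export
trim_histogram <- function(hist, alpha) {
  stopifnot(inherits(hist, "trs_histogram"))
  if (alpha < 0 || alpha >= 0.5) stop("alpha must be in [0, 0.5)", call. = FALSE)
  if (alpha == 0) return(hist)
  cp <- cumsum(hist$p)
  cp0 <- c(0, cp[-hist$n])
  w <- pmax(0, pmin(cp, 1 - alpha) - pmax(cp0, alpha))
  new_histogram(hist$mids, w / sum(w), w, hist$bin_edges)
}

# Prefix sums for O(1) class moments over bin ranges.
hist_state <- function(hist) {
  list(cp0 = c(0, cumsum(hist$p)),
       cpm0 = c(0, cumsum(hist$p * hist$mids)),
       n = hist$n)
}

# Probability mass and mean of bins [lo, hi], vectorized over parallel
# lo/hi vectors. Empty ranges give NA mean and weight 0.
range_stats <- function(st, lo, hi) {
  W <- st$cp0[hi + 1L] - st$cp0[lo]
  S <- st$cpm0[hi + 1L] - st$cpm0[lo]
  list(P = W, mu = ifelse(W > 0, S / W, NA_real_))
}

# Map a vector of gray-value thresholds to cut indices: cut c means the
# class boundary lies after bin c (bins with mid <= threshold fall below).
thresholds_to_cuts <- function(hist, thresholds) {
  if (length(thresholds) == 0L) return(integer(0))
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly ascending", call. = FALSE)
  }
  vapply(thresholds, function(t) sum(hist$mids <= t), integer(1))
}

# sigma^2 for one or many cut combinations on an (already trimmed)
# histogram state. `cuts` is a matrix with one row per combination and
# (M - 1) columns of ascending cut indices.
sigma2_for_cuts <- function(st, cuts, mu_T, printed_form = FALSE) {
  if (is.null(dim(cuts))) cuts <- matrix(cuts, nrow = 1L)
  M <- ncol(cuts) + 1L
  nn <- nrow(cuts)
  bounds <- cbind(0L, cuts, st$n)   # c_0 = 0, c_M = n
  sigma2 <- numeric(nn)
  for (i in seq_len(M)) {
    cs <- range_stats(st, bounds[, i] + 1L, bounds[, i + 1L])
    dev <- ifelse(is.na(cs$mu), 0, cs$mu - mu_T)
    sigma2 <- sigma2 + cs$P * (if (printed_form) dev else dev^2)
  }
  sigma2
}

#' Alpha-trimmed between-class variance of a thresholded histogram
#'
#' For classes defined by the thresholds, computes
#' \deqn{\sigma^2 = \sum_{i=1}^{M} P_i (\mu_i - \mu_T)^2,}
#' where \eqn{P_i} is the class probability, \eqn{\mu_i} the class mean and
#' \eqn{\mu_T} the total mean, all evaluated on the globally alpha-trimmed
#' histogram ([trim_histogram()]): trimming removes impulse-noise mass from
#' the tails before any class statistic is formed, which is what makes the
#' criterion robust to salt-and-pepper corruption. `printed_form = TRUE`
#' drops the square and returns \eqn{\sum_i P_i (\mu_i - \mu_T)} instead —
#' this linear form is offered only for comparison; it is identically 0
#' whatever the thresholds (the class means average to the total mean), so
#' it is not used by the optimizer by default.
#'
#' @param hist a `trs_histogram`.
#' @param thresholds ascending gray values inside the histogram support
#'   (possibly empty, giving the degenerate single class and sigma^2 = 0).
#' @param alpha trim fraction in \[0, 0.5).
#' @param printed_form use the linear (unsquared) form.
#' @return The between-class variance (scalar).
#' @examples
#' h <- histogram_from_probs(c(0.2, 0.8), c(0.5, 0.5))
#' between_class_variance(h, 0.5)  # 0.09
#' @export
between_class_variance <- function(hist, thresholds = numeric(0), alpha = 0,
                                   printed_form = FALSE) {
  stopifnot(inherits(hist, "trs_histogram"))
  if (alpha < 0 || alpha >= 0.5) stop("alpha must be in [0, 0.5)", call. = FALSE)
  cuts <- thresholds_to_cuts(hist, thresholds)
  st <- hist_state(trim_histogram(hist, alpha))
  mu_T <- range_stats(st, 1L, st$n)$mu
  if (length(cuts) == 0L) return(0)
  as.numeric(sigma2_for_cuts(st, matrix(cuts, nrow = 1L), mu_T,
                             printed_form))
}

# Lexicographically ordered (M-1)-tuples of ascending cut indices in 1..nc.
cut_combinations <- function(nc, M) {
  if (M == 2L) {
    matrix(seq_len(nc), ncol = 1L)
  } else if (M == 3L) {
    c1 <- rep(seq_len(nc - 1L), times = (nc - 1L):1L)
    c2 <- sequence((nc - 1L):1L) + c1
    cbind(c1, c2, deparse.level = 0)
  } else {
    stop("internal: cut_combinations only enumerates M <= 3 directly")
  }
}

#' Multilevel threshold selection by exhaustive variance maximization
#'
#' Searches every placement of `M - 1` thresholds on the histogram's bin
#' boundaries and returns the set maximizing the between-class variance of
#' the globally alpha-trimmed histogram ([between_class_variance()]). The
#' search is exhaustive for `M <= 4` (the supported range); ties are broken
#' toward the lexicographically smallest threshold vector, making the output
#' deterministic. With `alpha = 0` and `M = 2` this is exactly the classical
#' Otsu criterion; for any `alpha`, maximizing this criterion is equivalent
#' to minimizing the pooled intraclass variance of the trimmed histogram.
#'
#' @inheritParams between_class_variance
#' @param M number of classes, 2..4.
#' @return A list: `thresholds` (gray values at bin boundaries), `sigma2`,
#'   `cuts` (bin indices), `M`, `alpha`.
#' @export
multilevel_threshold <- function(hist, M = 3, alpha = 0.1) {
  stopifnot(inherits(hist, "trs_histogram"))
  M <- as.integer(M)
  if (M < 2L || M > 4L) stop("M must be between 2 and 4", call. = FALSE)
  if (alpha < 0 || alpha >= 0.5) stop("alpha must be in [0, 0.5)", call. = FALSE)
  if (sum(hist$p > 0) < M) {
    stop("histogram has fewer nonempty bins than classes",
         call. = FALSE)
  }
  st <- hist_state(trim_histogram(hist, alpha))
  mu_T <- range_stats(st, 1L, st$n)$mu
  nc <- st$n - 1L                       # candidate cuts: after bins 1..n-1
  if (M <= 3L) {
    combos <- cut_combinations(nc, M)
    s2 <- sigma2_for_cuts(st, combos, mu_T)
    best <- which.max(s2)
    cuts <- combos[best, ]
    sigma2 <- s2[best]
  } else {
    # M = 4: outer loop over the first cut, vectorized pairs inside;
    # lexicographic order is preserved so which.max tie-breaks correctly.
    sigma2 <- -Inf
    cuts <- NULL
    for (c1 in seq_len(nc - 2L)) {
      rest <- cut_combinations(nc - c1, 3L) + c1
      combos <- cbind(c1, rest, deparse.level = 0)
      s2 <- sigma2_for_cuts(st, combos, mu_T)
      b <- which.max(s2)
      if (s2[b] > sigma2) {
        sigma2 <- s2[b]
        cuts <- combos[b, ]
      }
    }
  }
  list(thresholds = as.numeric(hist$bin_edges[cuts + 1L]),
       sigma2 = as.numeric(sigma2), cuts = as.integer(cuts),
       M = M, alpha = alpha)
}

#' Segment the tumor ROI of one slice into intensity levels
#'
#' Builds a histogram from ROI pixels only (`bins` uniform bins over the
#' ROI's intensity range), picks thresholds with [multilevel_threshold()],
#' and labels every ROI pixel with its class (1..M, darkest first); pixels
#' outside the ROI get label 0 (background).
#'
#' @param image numeric matrix, the (enhanced) slice.
#' @param mask logical matrix, the tumor ROI.
#' @param M number of intensity classes within the ROI.
#' @param alpha trim fraction for the class statistics.
#' @param bins histogram bins.
#' @return A `trs_segmentation`: `thresholds`, `num_classes`, `class_means`,
#'   `class_probs`, `mu_T`, `between_class_variance`, `label_map`, `alpha`,
#'   `histogram`.
#' @export
segment_slice <- function(image, mask, M = 3, alpha = 0.1, bins = 256) {
  stopifnot_matrix(image)
  if (!is.logical(mask)) mask <- mask > 0
  if (!identical(dim(image), dim(mask))) {
    stop("image and mask shapes differ", call. = FALSE)
  }
  vals <- image[mask]
  if (length(vals) == 0L) stop("empty ROI", call. = FALSE)
  if (length(unique(vals)) < M || diff(range(vals)) == 0) {
    stop(structure(
      list(message = sprintf(
             "ROI has fewer than M = %d distinct gray values; reduce M", M),
           call = sys.call(-1)),
      class = c("trs_degenerate_roi", "error", "condition")))
  }
  hist <- intensity_histogram(vals, bins = bins)
  th <- multilevel_threshold(hist, M = M, alpha = alpha)
  label <- matrix(0L, nrow(image), ncol(image))
  cls <- rep(1L, length(vals))
  for (t in th$thresholds) cls <- cls + (vals > t)
  label[mask] <- cls
  st <- hist_state(trim_histogram(hist, alpha))
  bounds <- c(0L, th$cuts, hist$n)
  cs <- range_stats(st, bounds[-length(bounds)] + 1L, bounds[-1])
  mu_T <- range_stats(st, 1L, hist$n)$mu
  structure(
    list(thresholds = th$thresholds, num_classes = th$M,
         class_means = cs$mu, class_probs = cs$P, mu_T = mu_T,
         between_class_variance = th$sigma2, label_map = label,
         alpha = alpha, bins = bins, histogram = hist),
    class = "trs_segmentation"
  )
}

#' @export
print.trs_segmentation <- function(x, ...) {
  cat(sprintf("<trs_segmentation> M = %d, alpha = %g, thresholds: %s, sigma^2 = %.5g\n",
              x$num_classes, x$alpha,
              paste(signif(x$thresholds, 4), collapse = ", "),
              x$between_class_variance))
  invisible(x)
}
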