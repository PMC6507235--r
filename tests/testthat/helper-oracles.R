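# Independent oracles and fixture builders shared across test files.
# These deliberately avoid the package's internal code paths: trimming is
# done by explicit accumulation, and the threshold search is a plain brute
# force with naive per-class sums.

# Global alpha-trim of a probability vector by explicit accumulation.
oracle_trim <- function(p, alpha) {
  if (alpha == 0) return(p / sum(p))
  n <- length(p)
  w <- numeric(n)
  acc <- 0
  for (b in seq_len(n)) {
    lo <- acc
    hi <- acc + p[b]
    w[b] <- max(0, min(hi, 1 - alpha) - max(lo, alpha))
    acc <- hi
  }
  w / sum(w)
}

# Exhaustive-search argmax of the between-class variance over all cut
# combinations; returns the (lexicographically first) best cut vector.
oracle_best_cuts <- function(p, mids, M, alpha) {
  w <- oracle_trim(p / sum(p), alpha)
  n <- length(p)
  mu_T <- sum(w * mids)
  combos <- if (M == 2) matrix(seq_len(n - 1), ncol = 1) else
    t(utils::combn(n - 1, M - 1))
  best <- -Inf
  bc <- NULL
  for (r in seq_len(nrow(combos))) {
    cuts <- combos[r, ]
    b <- c(0, cuts, n)
    s2 <- 0
    for (i in seq_len(M)) {
      seg <- (b[i] + 1):b[i + 1]
      P <- sum(w[seg])
      if (P > 0) s2 <- s2 + P * (sum(w[seg] * mids[seg]) / P - mu_T)^2
    }
    if (s2 > best) {
      best <- s2
      bc <- cuts
    }
  }
  list(cuts = bc, sigma2 = best)
}

# Classical Otsu on a histogram: maximize w0 * w1 * (mu0 - mu1)^2 — a
# different algebraic form of the same two-class criterion.
oracle_otsu <- function(p, mids) {
  p <- p / sum(p)
  n <- length(p)
  best <- -Inf
  bc <- NA_integer_
  for (t in seq_len(n - 1)) {
    w0 <- sum(p[1:t])
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:t] * mids[1:t]) / w0
    mu1 <- sum(p[(t + 1):n] * mids[(t + 1):n]) / w1
    crit <- w0 * w1 * (mu0 - mu1)^2
    if (crit > best) {
      best <- crit
      bc <- t
    }
  }
  list(cut = bc, sigma2 = best)
}

# Random spiky histogram on [0, 1] with the requested number of bins.
rand_hist <- function(bins = 64) {
  p <- stats::rgamma(bins, 0.5)
  histogram_from_probs(seq(0, 1, length.out = bins), p / sum(p))
}

# Step-edge fixture: left half `lo`, right half `hi`.
step_image <- function(n = 64, lo = 0.2, hi = 0.8) {
  img <- matrix(lo, n, n)
  img[, (n / 2 + 1):n] <- hi
  img
}

# Asymmetric bimodal pixel sample (modes 0.3 / 0.6) clipped to [0, 1]; the
# asymmetry means an untrimmed threshold is dragged by a salt spike at 1.
bimodal_sample <- function(n1 = 2400, n2 = 1600) {
  pmin(1, pmax(0, c(stats::rnorm(n1, 0.3, 0.05), stats::rnorm(n2, 0.6, 0.05))))
}

# Mean column index of the half-max crossing of a step-like image.
edge_crossing <- function(img, rows, thresh = 0.5) {
  mean(apply(img[rows, , drop = FALSE], 1, function(r) which(r > thresh)[1]))
}
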