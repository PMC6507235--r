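test_that("alpha-trimmed sample statistics match hand-computed order statistics", {
  st <- alpha_trimmed_stats(c(1, 2, 3, 4, 100), 0.2)  # trims 1 and 100
  expect_equal(st$trimmed_mean, 3)
  expect_equal(st$trimmed_variance, stats::var(c(2, 3, 4)))
  # alpha = 0 reduces to the ordinary moments
  set.seed(2)
  v <- rnorm(50)
  st0 <- alpha_trimmed_stats(v, 0)
  expect_equal(st0$trimmed_mean, mean(v))
  expect_equal(st0$trimmed_variance, stats::var(v))
  # constant input
  stc <- alpha_trimmed_stats(rep(7, 9), 0.3)
  expect_equal(stc$trimmed_mean, 7)
  expect_equal(stc$trimmed_variance, 0)
  expect_error(alpha_trimmed_stats(numeric(0), 0.1), "empty")
  expect_error(alpha_trimmed_stats(1:5, 0.5), "alpha")
})

test_that("between-class variance matches closed forms", {
  h <- histogram_from_probs(c(0.2, 0.8), c(0.5, 0.5))
  expect_equal(between_class_variance(h, 0.5),
               0.5 * (0.2 - 0.5)^2 + 0.5 * (0.8 - 0.5)^2)  # 0.09
  # degenerate single class
  expect_equal(between_class_variance(h), 0)
  # all mass on one side of the threshold
  expect_equal(between_class_variance(h, 0.9), 0)
  expect_error(between_class_variance(h, c(0.6, 0.4)), "ascending")
})

test_that("the printed linear criterion form is identically zero", {
  set.seed(14)
  for (i in 1:20) {
    h <- rand_hist(32)
    th <- sort(sample(h$mids[-32], 2))
    for (al in c(0, 0.1, 0.25)) {
      expect_equal(between_class_variance(h, th, alpha = al,
                                          printed_form = TRUE),
                   0, tolerance = 1e-12)
    }
  }
})

test_that("sigma^2 is invariant to empty bins and bounded by total variance", {
  set.seed(31)
  for (i in 1:20) {
    p <- rgamma(16, 1)
    mids <- seq(0.1, 0.9, length.out = 16)
    h <- histogram_from_probs(mids, p / sum(p))
    # interleave empty bins at new mid positions
    mids2 <- sort(c(mids, mids + diff(mids)[1] / 3))
    p2 <- numeric(32)
    p2[match(mids, mids2)] <- p / sum(p)
    h2 <- histogram_from_probs(mids2, p2)
    th <- c(0.35, 0.63)
    for (al in c(0, 0.1)) {
      s1 <- between_class_variance(h, th, alpha = al)
      expect_equal(between_class_variance(h2, th, alpha = al), s1,
                   tolerance = 1e-12)
      ht <- trim_histogram(h, al)
      total_var <- sum(ht$p * (ht$mids - ht$mu_T)^2)
      expect_lte(s1, total_var + 1e-12)
    }
  }
})

test_that("bimodal and trimodal thresholds coincide with the exhaustive oracle", {
  set.seed(5)
  v <- c(rnorm(600, 0.25, 0.04), rnorm(600, 0.75, 0.04))
  h <- intensity_histogram(v, bins = 64)
  got <- multilevel_threshold(h, M = 2, alpha = 0)
  want <- oracle_best_cuts(h$p, h$mids, 2, 0)
  expect_identical(got$cuts, as.integer(want$cuts))
  expect_gt(got$thresholds, 0.35)   # between the modes at 0.25 and 0.75
  expect_lt(got$thresholds, 0.65)

  v3 <- c(rnorm(500, 0.15, 0.03), rnorm(500, 0.5, 0.03),
          rnorm(500, 0.85, 0.03))
  h3 <- intensity_histogram(v3, bins = 64)
  got3 <- multilevel_threshold(h3, M = 3, alpha = 0.1)
  want3 <- oracle_best_cuts(h3$p, h3$mids, 3, 0.1)
  expect_identical(got3$cuts, as.integer(want3$cuts))
  expect_true(got3$thresholds[1] > 0.2 && got3$thresholds[1] < 0.45)
  expect_true(got3$thresholds[2] > 0.55 && got3$thresholds[2] < 0.8)
})

test_that("threshold search equals the oracle on random histograms (M 2..4)", {
  set.seed(77)
  for (i in 1:25) {
    h <- rand_hist(64)
    for (M in 2:3) {
      for (al in c(0, 0.1)) {
        got <- multilevel_threshold(h, M, al)
        want <- oracle_best_cuts(h$p, h$mids, M, al)
        expect_identical(got$cuts, as.integer(want$cuts))
        expect_equal(got$sigma2, want$sigma2, tolerance = 1e-12)
      }
    }
  }
  # the M = 4 looped path against the plain combn oracle on smaller bins
  for (i in 1:5) {
    h <- rand_hist(20)
    got <- multilevel_threshold(h, 4, 0.1)
    want <- oracle_best_cuts(h$p, h$mids, 4, 0.1)
    expect_identical(got$cuts, as.integer(want$cuts))
  }
})

test_that("alpha = 0 reproduces the classical Otsu criterion exactly", {
  set.seed(19)
  for (i in 1:50) {
    h <- rand_hist(64)
    got <- multilevel_threshold(h, M = 2, alpha = 0)
    want <- oracle_otsu(h$p, h$mids)
    expect_identical(got$cuts, as.integer(want$cut))
    expect_lt(abs(got$sigma2 - want$sigma2), 1e-12)
  }
})

test_that("trimmed thresholds resist salt-and-pepper noise better", {
  set.seed(42)
  clean <- bimodal_sample()
  h0 <- intensity_histogram(clean, bins = 128, range = c(0, 1))
  base0 <- multilevel_threshold(h0, 2, 0)$thresholds
  base1 <- multilevel_threshold(h0, 2, 0.1)$thresholds
  wins <- 0
  for (rep in 1:100) {
    noisy <- clean
    idx <- sample(length(noisy), round(0.05 * length(noisy)))
    noisy[idx] <- sample(c(0, 1), length(idx), replace = TRUE)
    hn <- intensity_histogram(noisy, bins = 128, range = c(0, 1))
    d0 <- abs(multilevel_threshold(hn, 2, 0)$thresholds - base0)
    d1 <- abs(multilevel_threshold(hn, 2, 0.1)$thresholds - base1)
    wins <- wins + (d1 < d0)
  }
  expect_gte(wins, 90)
})

test_that("segment_slice reproduces a known two-tone partition exactly", {
  img <- matrix(0.2, 64, 64)
  mask <- matrix(FALSE, 64, 64)
  mask[16:48, 16:48] <- TRUE
  img[16:48, 16:32] <- 0.3
  img[16:48, 33:48] <- 0.7
  seg <- segment_slice(img, mask, M = 2, alpha = 0)
  expect_true(all(seg$label_map[16:48, 16:32] == 1))
  expect_true(all(seg$label_map[16:48, 33:48] == 2))
  expect_true(all(seg$label_map[!mask] == 0))
  # stored sigma^2 is consistent with (P_i, mu_i, mu_T)
  recomputed <- sum(seg$class_probs * (seg$class_means - seg$mu_T)^2)
  expect_equal(seg$between_class_variance, recomputed, tolerance = 1e-9)
})

test_that("segment_slice flags degenerate ROIs and is deterministic", {
  img <- matrix(0.5, 32, 32)
  mask <- matrix(TRUE, 32, 32)
  expect_error(segment_slice(img, mask, M = 2), class = "trs_degenerate_roi")
  set.seed(3)
  img2 <- matrix(runif(32 * 32), 32, 32)
  s1 <- segment_slice(img2, mask, M = 3)
  s2 <- segment_slice(img2, mask, M = 3)
  expect_identical(s1, s2)
  expect_error(segment_slice(img2, mask * 0 > 0, M = 2), "empty ROI")
})
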