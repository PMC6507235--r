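test_that("edge detection returns the 4-connectivity inner boundary", {
  m <- matrix(FALSE, 20, 20)
  m[6:15, 6:15] <- TRUE                     # 10x10 square
  expect_equal(nrow(detect_edges(m)$points), 4 * 10 - 4)
  # single pixel is its own boundary
  p1 <- matrix(FALSE, 5, 5); p1[3, 3] <- TRUE
  expect_equal(detect_edges(p1)$points, cbind(3L, 3L))
  # full-frame region: border ring only
  full <- matrix(TRUE, 12, 9)
  expect_equal(nrow(detect_edges(full)$points), 2 * (12 + 9) - 4)
  expect_error(detect_edges(matrix(FALSE, 4, 4)), "empty")
  # level selection from a label map
  lab <- matrix(0L, 8, 8); lab[3:6, 3:6] <- 2L
  expect_equal(nrow(detect_edges(lab, level = 2)$points), 12)
})

test_that("box counts match hand-enumerated grids", {
  # one point occupies one box at every size
  one <- box_count(cbind(5L, 7L), c(1, 3, 9), n_offsets = 1)
  expect_true(all(one$counts == 1))
  # four corners of a square of side 10 (11 px extent)
  pts <- rbind(c(1, 1), c(1, 11), c(11, 1), c(11, 11))
  expect_equal(box_count(pts, 10, n_offsets = 1)$counts, 4)
  expect_equal(box_count(pts, 21, n_offsets = 1)$counts, 1)
  # collinear points spanning L pixels: N ~ L / delta
  L <- 96
  line <- cbind(1L, seq_len(L))
  cv <- box_count(line, c(2, 4, 8, 16), n_offsets = 1)
  for (k in seq_along(cv$box_sizes)) {
    expect_lte(abs(cv$counts[k] - L / cv$box_sizes[k]), 1)
  }
  expect_error(box_count(line[0, , drop = FALSE], 2), "non-empty")
  expect_error(box_count(line, c(0, 2)), "positive")
})

test_that("box-count curves are monotone for random point clouds", {
  set.seed(12)
  for (i in 1:50) {
    pts <- cbind(sample(200, 80, TRUE), sample(200, 80, TRUE))
    cv <- box_count(pts, c(2, 4, 8, 16, 32), n_offsets = 4)
    expect_true(all(diff(cv$counts) >= 0))  # stored descending in delta
    expect_true(all(cv$counts >= 1))
    expect_lte(cv$counts[length(cv$counts)], nrow(unique(pts)))
  }
})

test_that("dimension fit recovers exact power laws and flags bad input", {
  sizes <- c(1, 2, 4, 8)
  cv <- boxcount_curve(sizes, (1 / sizes)^1.5 * 500)
  ft <- fit_dimension(cv)
  expect_equal(ft$slope, 1.5, tolerance = 1e-12)
  expect_equal(ft$r_squared, 1, tolerance = 1e-12)
  # constant counts: slope 0
  ftc <- fit_dimension(boxcount_curve(sizes, rep(7, 4)))
  expect_equal(ftc$slope, 0)
  expect_error(fit_dimension(boxcount_curve(c(2, 4), c(4, 2))), "3 distinct")
})

test_that("smooth closed boundaries score near dimension one", {
  n <- 128
  d <- sqrt(outer((1:n - 64.5)^2, (1:n - 64.5)^2, "+"))
  disk <- d <= 36
  ep <- detect_edges(disk)
  ft <- fit_dimension(box_count(ep, c(2, 4, 8, 16)))
  expect_equal(ft$slope, 1, tolerance = 0.1)
})

test_that("congruent levels give a slice score equal to the level score", {
  img <- matrix(0.1, 64, 64)
  mask <- matrix(FALSE, 64, 64)
  mask[10:55, 5:30] <- TRUE
  mask[10:55, 35:60] <- TRUE
  img[10:55, 5:30] <- 0.3      # level 1: 46x26 rectangle
  img[10:55, 35:60] <- 0.7     # level 2: congruent rectangle
  seg <- segment_slice(img, mask, M = 2, alpha = 0)
  sc <- score_slice(seg, box_sizes = c(2, 4, 8, 16))
  expect_equal(nrow(sc$levels), 2)
  expect_equal(sc$levels$slope[1], sc$levels$slope[2], tolerance = 1e-9)
  expect_equal(sc$score, sc$levels$slope[1], tolerance = 1e-9)
})

test_that("rougher phantoms score higher than smooth ones", {
  r <- sapply(c(0, 0.3), function(a) {
    ph <- make_tumor_phantom(phantom_spec(perturb_amplitude = a, seed = 6))
    tumor_roughness_score(ph$stack, ph$mask)$R_avg
  })
  expect_gt(r[2], r[1])
})

test_that("single-slice TRS equals the slice score; skipping and errors work", {
  ph <- make_tumor_phantom(phantom_spec(n_slices = 1, seed = 2))
  res <- tumor_roughness_score(ph$stack, ph$mask)
  expect_equal(res$R_avg, res$per_slice$score[1])
  # a slice with a tiny ROI is skipped
  ph3 <- make_tumor_phantom(phantom_spec(n_slices = 2, seed = 2))
  tiny <- ph3$mask$slices[[2]] & FALSE
  tiny[96:98, 96:98] <- TRUE   # 9 px < min_roi_pixels
  ph3$mask$slices[[2]] <- tiny
  res3 <- tumor_roughness_score(ph3$stack, ph3$mask)
  expect_equal(res3$skipped, 2L)
  expect_equal(nrow(res3$per_slice), 1)
  # no usable slice at all
  alltiny <- lapply(ph3$mask$slices, function(m) {
    z <- m & FALSE; z[5, 5] <- TRUE; z
  })
  expect_error(
    tumor_roughness_score(ph3$stack, roi_mask(alltiny)), "usable ROI")
})

test_that("the full pipeline is bit-identical across runs", {
  ph <- make_tumor_phantom(phantom_spec(perturb_amplitude = 0.25, seed = 13))
  r1 <- tumor_roughness_score(ph$stack, ph$mask)
  r2 <- tumor_roughness_score(ph$stack, ph$mask)
  expect_identical(r1, r2)
})

test_that("whole-pixel translations barely change the score", {
  ph <- make_tumor_phantom(phantom_spec(n_slices = 1, perturb_amplitude = 0.2,
                                        seed = 9))
  img <- ph$stack$slices[[1]]
  m <- ph$mask$slices[[1]]
  shift <- function(x, dr, dc, fill) {
    out <- matrix(fill, nrow(x), ncol(x))
    out[(1 + dr):nrow(x), (1 + dc):ncol(x)] <-
      x[1:(nrow(x) - dr), 1:(ncol(x) - dc)]
    out
  }
  r0 <- tumor_roughness_score(img, m)$R_avg
  r1 <- tumor_roughness_score(shift(img, 3, 5, 0.2), shift(m, 3, 5, FALSE))$R_avg
  expect_lt(abs(r1 - r0), 0.02)
})
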