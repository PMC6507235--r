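test_that("ANOVA with LSD matches closed forms and standard oracles", {
  # identical groups: no between-group signal
  rec <- data.frame(y = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  res <- anova_lsd(rec, "y", "g")
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  # zero within-group variance: degenerate with warning
  rec0 <- data.frame(y = c(0, 0, 1, 1), g = rep(c("a", "b"), each = 2))
  w <- testthat::capture_warnings(res0 <- anova_lsd(rec0, "y", "g"))
  expect_true(any(grepl("zero within-group", w)))
  expect_equal(res0$lsd$p, 0)
  # two-group F equals the squared pooled t statistic
  set.seed(4)
  for (i in 1:20) {
    d <- data.frame(y = rnorm(30), g = rep(c("a", "b"), c(12, 18)))
    a <- anova_lsd(d, "y", "g")
    tt <- stats::t.test(y ~ g, data = d, var.equal = TRUE)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(a$p, tt$p.value, tolerance = 1e-9)
    # with two groups the LSD p equals the overall ANOVA p
    expect_equal(a$lsd$p, a$p, tolerance = 1e-9)
  }
  # LSD pairwise p-values equal unadjusted pooled-sd pairwise t tests
  set.seed(9)
  d4 <- data.frame(y = rnorm(40, rep(c(0, 0.5, 1, 2), each = 10)),
                   g = rep(letters[1:4], each = 10))
  a4 <- anova_lsd(d4, "y", "g")
  pw <- stats::pairwise.t.test(d4$y, d4$g, p.adjust.method = "none",
                               pool.sd = TRUE)
  for (k in seq_len(nrow(a4$lsd))) {
    i <- a4$lsd$group2[k]; j <- a4$lsd$group1[k]
    want <- pw$p.value[i, j]
    if (is.na(want)) want <- pw$p.value[j, i]
    expect_equal(a4$lsd$p[k], unname(want), tolerance = 1e-9)
  }
  expect_error(anova_lsd(data.frame(y = 1:3, g = "a"), "y", "g"),
               "two groups")
})

test_that("Pearson test matches exact correlations and rejects bad input", {
  d <- data.frame(x = 1:10, y = 1:10)
  expect_equal(pearson_test(d, "x", "y")$r, 1)
  d2 <- data.frame(x = 1:10, y = -2 * (1:10))
  expect_equal(pearson_test(d2, "x", "y")$r, -1)
  expect_error(pearson_test(data.frame(x = rep(1, 5), y = 1:5), "x", "y"),
               "constant")
  expect_error(pearson_test(data.frame(x = 1:2, y = 2:1), "x", "y"), "n >= 3")
})

test_that("null correlations stay inside the critical band", {
  # at n = 27 the two-tailed 5% critical |r| is 0.381 (df = 25)
  set.seed(6)
  inside <- mean(replicate(400, {
    abs(stats::cor(rnorm(27), rnorm(27))) < 0.381
  }))
  expect_gt(inside, 0.90)
  expect_lt(inside, 0.99)
})

test_that("linear model recovers exact coefficients and reports rank problems", {
  d <- data.frame(y = 2 * (1:20) + 3, x1 = 1:20)
  # the exact fit triggers R's perfect-fit caveat; the point is the values
  lmres <- suppressWarnings(linear_model(d, "y", "x1"))
  expect_equal(lmres$coefficients$estimate, c(3, 2), tolerance = 1e-9)
  expect_lt(lmres$coefficients$p[2], 1e-12)
  # duplicated covariate: rank deficiency named
  d$x2 <- d$x1
  expect_error(linear_model(d, "y", c("x1", "x2")), "x2")
  # residuals orthogonal to every covariate column
  set.seed(11)
  n <- 60
  d3 <- data.frame(y = rnorm(n), a = scale(rnorm(n))[, 1],
                   b = scale(rnorm(n))[, 1], c = scale(rnorm(n))[, 1])
  fit <- linear_model(d3, "y", c("a", "b", "c"))
  e <- stats::residuals(fit$fit)
  expect_lt(max(abs(crossprod(as.matrix(d3[, c("a", "b", "c")]), e))), 1e-8)
  # logical covariates are accepted
  d4 <- data.frame(y = rnorm(30), f = rep(c(TRUE, FALSE), 15))
  expect_silent(linear_model(d4, "y", "f"))
  expect_error(linear_model(d4[1:2, ], "y", "f"), "covariates")
})

test_that("subtype aggressiveness coding follows the roughness ordering", {
  expect_equal(subtype_code(c("benign_cyst", "oncocytoma", "chromophobe",
                              "clear_cell", "papillary")), 0:4)
  expect_error(subtype_code("sarcoma"), "unknown")
})

test_that("cohort summary reproduces the published overall percentages", {
  coh <- renal_cohort_27()
  expect_equal(nrow(coh), 27)
  expect_equal(as.vector(table(coh$subtype)), c(1, 2, 2, 15, 7))
  s <- cohort_summary(coh)
  expect_equal(s$overall$pct_male, 93)    # 25/27 men
  expect_equal(s$overall$pct_white, 59)   # 16/27 of European descent
  expect_equal(s$overall$n_male, 25)
  expect_equal(s$overall$n_white, 16)
  expect_equal(nrow(s$by_subtype), 5)
})

test_that("cohort summary of a single record echoes its values", {
  one <- data.frame(subtype = "clear_cell", age = 50, trs = 1.4, male = TRUE)
  s <- cohort_summary(one)
  expect_equal(s$overall$median_age, 50)
  expect_equal(s$overall$iqr_age, c(50, 50))
  expect_equal(s$overall$pct_male, 100)
  expect_error(cohort_summary(one[0, ]), "empty")
})
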