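#' One-way ANOVA with LSD post hoc comparisons
#'
#' Fits the one-way ANOVA of `value_field` across `group_field` and
#' computes Fisher's least-significant-difference (LSD) pairwise table: for
#' every pair of groups, a t test of the mean difference on the pooled
#' within-group variance with the ANOVA residual degrees of freedom, with
#' NO multiplicity correction (that is what LSD means). With only two
#' groups the LSD p-value equals the overall ANOVA p.
#'
#' @param records data.frame of one row per subject.
#' @param value_field name of the numeric outcome column.
#' @param group_field name of the grouping column.
#' @return A list: `F`, `p`, `df` (between, within), and `lsd` (data.frame
#'   with `group1`, `group2`, `diff`, `se`, `t`, `p`, `lower`, `upper`).
#' @examples
#' coh <- make_synthetic_cohort(8, c(1.2, 1.2, 1.5), group_sd = 0.1, seed = 2)
#' anova_lsd(coh, "trs", "subtype")$p
#' @export
anova_lsd <- function(records, value_field = "trs", group_field = "subtype") {
  y <- records[[value_field]]
  g <- factor(records[[group_field]])
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (!any(table(g) >= 2L)) {
    stop("need at least one group with >= 2 observations", call. = FALSE)
  }
  fit <- stats::lm(y ~ g)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df_w <- an["Residuals", "Df"]
  # exact-fit designs leave residuals at rounding level only
  zero_within <- mse < max(1e-12 * stats::var(y), 1e-300)
  if (zero_within) {
    warning("zero within-group variance; p-values degenerate to 0")
    mse <- 0
  }
  means <- tapply(y, g, mean)
  ns <- tabulate(g)
  pairs <- utils::combn(nlevels(g), 2)
  lsd <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    d <- means[i] - means[j]
    se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    tval <- if (se > 0) d / se else sign(d) * Inf
    p <- if (se > 0) 2 * stats::pt(-abs(tval), df_w) else as.numeric(d == 0)
    tc <- stats::qt(0.975, df_w)
    data.frame(group1 = levels(g)[i], group2 = levels(g)[j],
               diff = unname(d), se = se, t = unname(tval), p = unname(p),
               lower = unname(d - tc * se), upper = unname(d + tc * se))
  }))
  list(F = an[1, "F value"], p = an[1, "Pr(>F)"],
       df = c(between = an[1, "Df"], within = df_w), lsd = lsd)
}

#' Pearson correlation test
#'
#' Sample Pearson correlation of two cohort columns with the two-tailed
#' t-based p-value (wraps `cor.test`).
#'
#' @param records data.frame.
#' @param x_field,y_field column names (e.g. tumor size vs. TRS).
#' @return A list: `r`, `p`, `n`.
#' @export
pearson_test <- function(records, x_field = "tumor_size", y_field = "trs") {
  x <- records[[x_field]]; y <- records[[y_field]]
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("constant input has no defined correlation", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Multivariable linear regression
#'
#' Ordinary least squares of `outcome` on `covariates` with an intercept;
#' two-tailed t p-values and 95% confidence intervals per coefficient.
#' Rank-deficient designs are rejected with the name of the offending
#' covariate.
#'
#' @param records data.frame.
#' @param outcome outcome column name.
#' @param covariates character vector of covariate column names.
#' @return A list: `coefficients` (data.frame with `term`, `estimate`,
#'   `lower`, `upper`, `t`, `p`), `fit` (the `lm` object), `r_squared`.
#' @export
linear_model <- function(records, outcome, covariates) {
  if (nrow(records) <= length(covariates) + 1L) {
    stop("need n > number of covariates + 1", call. = FALSE)
  }
  X <- records[, covariates, drop = FALSE]
  # logicals enter as 0/1
  for (v in covariates) if (is.logical(X[[v]])) X[[v]] <- as.numeric(X[[v]])
  df <- cbind(.y = records[[outcome]], X)
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; offending covariate(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  co <- data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, "Estimate"],
    lower = ci[, 1], upper = ci[, 2],
    t = sm$coefficients[, "t value"],
    p = sm$coefficients[, "Pr(>|t|)"],
    row.names = NULL
  )
  list(coefficients = co, fit = fit, r_squared = sm$r.squared)
}

#' Encode renal-mass subtype as an ordered aggressiveness score
#'
#' benign_cyst = 0, oncocytoma = 1, chromophobe = 2, clear_cell = 3,
#' papillary = 4 — the ordering of the subtypes' mean roughness scores.
#' Modeling a categorical subtype with linear regression requires some
#' numeric coding; this ordered code is the documented choice, and
#' TRS-as-outcome is the statistically cleaner alternative when the goal is
#' inference rather than subtype prediction.
#'
#' @param subtype character or factor of subtype labels.
#' @return Integer vector in 0..4.
#' @export
subtype_code <- function(subtype) {
  levels_ordered <- c("benign_cyst", "oncocytoma", "chromophobe",
                      "clear_cell", "papillary")
  code <- match(as.character(subtype), levels_ordered) - 1L
  if (any(is.na(code))) stop("unknown subtype label", call. = FALSE)
  code
}

#' Per-subtype and overall cohort summary
#'
#' For each subtype: n, median (IQR) of the continuous fields, count and
#' percent of the logical fields; plus an overall row. Percentages are
#' rounded to the whole percent. Empty strata are reported blank.
#'
#' @param records data.frame with at least `subtype`; continuous and logical
#'   columns are summarized automatically.
#' @return A list: `by_subtype` (data.frame, one row per subtype),
#'   `overall` (named list with medians, IQRs and percentages, e.g.
#'   `pct_male`, `pct_white`).
#' @examples
#' cohort_summary(renal_cohort_27())$overall[c("pct_male", "pct_white")]
#' @export
cohort_summary <- function(records) {
  if (nrow(records) == 0L) stop("empty cohort", call. = FALSE)
  g <- factor(records$subtype)
  cont <- names(records)[vapply(records, is.numeric, logical(1))]
  flags <- names(records)[vapply(records, is.logical, logical(1))]
  med_iqr <- function(v) {
    if (length(v) == 0L) return("")
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
    sprintf("%.3g (%.3g-%.3g)", q[2], q[1], q[3])
  }
  pct <- function(v) {
    if (length(v) == 0L) return("")
    sprintf("%d/%d (%d%%)", sum(v), length(v), round(100 * mean(v)))
  }
  by_subtype <- do.call(rbind, lapply(levels(g), function(lev) {
    sub <- records[g == lev, , drop = FALSE]
    row <- data.frame(subtype = lev, n = nrow(sub))
    for (v in cont) row[[v]] <- med_iqr(sub[[v]])
    for (v in flags) row[[v]] <- pct(sub[[v]])
    row
  }))
  overall <- list(n = nrow(records))
  for (v in cont) {
    overall[[paste0("median_", v)]] <- stats::median(records[[v]], na.rm = TRUE)
    overall[[paste0("iqr_", v)]] <-
      unname(stats::quantile(records[[v]], c(0.25, 0.75), na.rm = TRUE))
  }
  for (v in flags) {
    overall[[paste0("n_", v)]] <- sum(records[[v]])
    overall[[paste0("pct_", v)]] <- round(100 * mean(records[[v]]))
  }
  list(by_subtype = by_subtype, overall = overall)
}

#' Reconstructed 27-patient renal-mass demographics
#'
#' A synthetic subject-level reconstruction of a published 27-patient
#' nephrectomy series' demographic table: subtype group sizes (benign cyst
#' 1, oncocytoma 2, chromophobe 2, clear cell 15, papillary 7), per-subtype
#' male counts (0/1, 1/2, 2/2, 15/15, 7/7), white counts (1/1, 1/2, 0/2,
#' 9/15, 5/7) and stage-3 counts (0, 0, 0, 1, 0). Continuous fields carry
#' the per-subtype medians (identical within subtype), so only counts,
#' percentages and medians of this table are meaningful — it is a fixture
#' for the summary layer, not real subject data.
#'
#' @return A data.frame with columns `subject_id`, `subtype`, `age`, `bmi`,
#'   `white`, `male`, `tumor_size`, `stage3`, `trs`.
#' @export
renal_cohort_27 <- function() {
  subtypes <- c("benign_cyst", "oncocytoma", "chromophobe", "clear_cell",
                "papillary")
  n <- c(1, 2, 2, 15, 7)
  males <- c(0, 1, 2, 15, 7)
  whites <- c(1, 1, 0, 9, 5)
  stage3 <- c(0, 0, 0, 1, 0)
  age <- c(60, 45, 54, 56, 57)
  bmi <- c(24.9, 26.3, 31.8, 30.1, 32.01)
  size <- c(1.8, 5.3, 4.45, 2.3, 2.5)
  trs <- c(1.18, 1.16, 1.27, 1.52, 1.56)
  rows <- lapply(seq_along(subtypes), function(i) {
    k <- n[i]
    data.frame(
      subtype = rep(subtypes[i], k),
      age = rep(age[i], k), bmi = rep(bmi[i], k),
      white = seq_len(k) <= whites[i],
      male = seq_len(k) <= males[i],
      tumor_size = rep(size[i], k),
      stage3 = seq_len(k) <= stage3[i],
      trs = rep(trs[i], k)
    )
  })
  out <- do.call(rbind, rows)
  out <- cbind(subject_id = sprintf("P%02d", seq_len(nrow(out))), out)
  out$subtype <- factor(out$subtype, levels = subtypes)
  out
}
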