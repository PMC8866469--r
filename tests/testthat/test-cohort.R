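# Cohort statistics: ROC/AUC, Fisher's exact test, Kruskal-Wallis with
# pairwise Mann-Whitney, Spearman correlation, severity report.

test_that("AUC hits the closed-form endpoints", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))$auc, 1)
  expect_equal(roc_auc(rep(5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "non-empty")
})

test_that("trapezoidal AUC equals the all-pairs U statistic exactly", {
  set.seed(31)
  for (rep in 1:10) {
    s <- round(c(rnorm(20, 1), rnorm(20)), 1)  # rounding forces ties
    lab <- rep(c(TRUE, FALSE), each = 20)
    expect_equal(roc_auc(s, lab)$auc, auc_allpairs(s, lab), tolerance = 1e-12)
  }
})

test_that("AUC is antisymmetric in orientation and matches pROC", {
  set.seed(37)
  s <- rnorm(30)
  lab <- runif(30) < 0.5
  lab[1:2] <- c(TRUE, FALSE)
  r1 <- roc_auc(s, lab, "higher")
  r2 <- roc_auc(s, lab, "lower")
  expect_equal(r1$auc + r2$auc, 1, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  pr <- pROC::roc(lab, s, direction = "<", quiet = TRUE)
  expect_equal(r1$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("ROC points are monotone and the CI brackets the AUC", {
  set.seed(41)
  r <- roc_auc(rnorm(40), rep(c(TRUE, FALSE), 20))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
  expect_true(r$auc >= 0 && r$auc <= 1)
})

test_that("Hanley-McNeil standard error matches the published formula", {
  s <- c(1, 3, 2, 6, 7, 5, 9)
  lab <- c(F, F, F, T, T, T, T)
  r <- roc_auc(s, lab)
  a <- r$auc
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + 3 * (q1 - a^2) + 2 * (q2 - a^2)) / 12)
  expect_equal(r$se, se, tolerance = 1e-12)
})

test_that("Fisher's exact test reproduces the printed severity contingency", {
  # 30/34 eyes with severe NPDR or PDR vs 19/41 milder eyes meeting the
  # high-ratio criterion
  res <- fisher_exact_2x2(matrix(c(30, 4, 19, 22), 2, 2, byrow = TRUE))
  expect_lt(res$p_value, 0.001)
  expect_equal(round(res$row_pct[1], 1), 88.2, ignore_attr = TRUE)
  expect_equal(round(res$row_pct[2], 1), 46.3, ignore_attr = TRUE)
  expect_equal(res$odds_ratio, 30 * 22 / (4 * 19), tolerance = 1e-12)
})

test_that("Fisher p matches enumeration, fisher.test, and symmetry properties", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2, 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 7), 2, 2, byrow = TRUE))$p_value, 1)
  set.seed(43)
  for (rep in 1:40) {
    tab <- matrix(rpois(4, 8), 2, 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(p, fisher_enum(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    expect_equal(p, fisher_exact_2x2(t(tab))$p_value, tolerance = 1e-12)
    expect_equal(p, fisher_exact_2x2(tab[2:1, 2:1])$p_value, tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2, 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(c(0.5, 1, 1, 1), 2, 2)), "integer")
})

test_that("Kruskal-Wallis and pairwise Mann-Whitney behave on canonical cases", {
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  r <- kruskal_pairwise(same)
  expect_lt(r$omnibus$statistic, 1e-8)
  expect_gt(r$omnibus$p, 0.99)
  sep <- list(lo = 1:4, hi = 11:14)
  rs <- kruskal_pairwise(sep)
  expect_equal(rs$pairwise$p_raw, 2 / choose(8, 4), tolerance = 1e-12)
  three <- list(a = rnorm(6), b = rnorm(6) + 1, c = rnorm(6) + 2)
  rt <- kruskal_pairwise(three)
  expect_identical(nrow(rt$pairwise), 3L)
  expect_equal(rt$pairwise$p_adj, pmin(1, rt$pairwise$p_raw * 3))
  expect_error(kruskal_pairwise(list(a = 1:3)), "at least 2")
})

test_that("two-group Kruskal-Wallis is consistent with Mann-Whitney on tie-free data", {
  set.seed(47)
  a <- rnorm(12)
  b <- rnorm(12) + 0.8
  kw <- kruskal_pairwise(list(a = a, b = b))
  mw <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(kw$omnibus$p, mw$p.value, tolerance = 1e-6)
})

test_that("group summaries report median and IQR", {
  r <- kruskal_pairwise(list(a = 1:5, b = c(2, 4, 6, 8)))
  expect_equal(r$summary$median, c(3, 5))
  expect_equal(r$summary$q1, c(2, 3.5))
  expect_equal(r$summary$q3, c(4, 6.5))
})

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  expect_equal(spearman_assoc(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_assoc(1:10, -(1:10))$rho, -1)
  set.seed(53)
  x <- rnorm(10)
  y <- rnorm(10)
  got <- spearman_assoc(x, y)
  expect_equal(got$rho, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  rho <- got$rho
  tref <- rho * sqrt(8 / (1 - rho^2))
  expect_equal(got$p, 2 * stats::pt(-abs(tref), 8), tolerance = 1e-12)
  expect_warning(res <- spearman_assoc(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$rho))
})

test_that("grade groupings implement the clinical comparison schemes", {
  g <- dr_grades()
  expect_equal(grade_grouping(g, "diabetic"), c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(grade_grouping(g, "any_dr"), c(NA, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(grade_grouping(g, "referable"), c(NA, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(grade_grouping(g, "severe_pdr"), c(NA, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(grade_grouping(g, "pdr_vs_npdr"), c(NA, NA, FALSE, FALSE, FALSE, TRUE))
  expect_error(grade_grouping("mild", "diabetic"), "invalid grade")
})

test_that("severity report handles single-grade cohorts and empty classes", {
  cohort <- data.frame(grade = rep("pdr", 6), total_count = rpois(6, 200),
                       mean_area_mm2 = runif(6))
  expect_warning(severity_report(cohort, parameters = "total_count",
                                 schemes = "pdr_vs_npdr"),
                 "empty class")
  rep1 <- suppressWarnings(severity_report(
    cohort, parameters = c("total_count", "mean_area_mm2"),
    schemes = "pdr_vs_npdr"))
  expect_identical(nrow(rep1$medians), 2L)
  expect_length(rep1$tests, 0)
  expect_length(rep1$roc$total_count, 0)
})

test_that("a permuted-label cohort gives near-chance AUC and a real one does not", {
  set.seed(59)
  count <- c(rnorm(40, 540, 40), rnorm(40, 280, 60))
  grade <- rep(c("nondiabetic", "moderate_npdr"), each = 40)
  cohort <- data.frame(grade = grade, total_count = count)
  rep1 <- severity_report(cohort, parameters = "total_count", schemes = "diabetic")
  expect_gt(rep1$roc$total_count$diabetic$auc, 0.95)
  for (k in 1:5) {
    sham <- cohort
    sham$grade <- sample(sham$grade)
    rep2 <- severity_report(sham, parameters = "total_count", schemes = "diabetic")
    expect_true(rep2$roc$total_count$diabetic$auc >= 0.35 &&
                  rep2$roc$total_count$diabetic$auc <= 0.65)
  }
})

test_that("the high-ratio contingency reduces a cohort to the printed-style 2x2", {
  cohort <- data.frame(
    grade = c(rep("severe_npdr", 3), rep("pdr", 2), rep("mild_npdr", 4)),
    count_ap_gt_0.025 = c(2, 0, 1, 3, 1, 0, 0, 1, 0))
  res <- high_ratio_contingency(cohort, "severe_pdr")
  expect_equal(unname(res$table), matrix(c(4, 1, 1, 3), 2, 2, byrow = TRUE))
})
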