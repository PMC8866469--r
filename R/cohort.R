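# Cohort-level statistics: nonparametric group comparisons, contingency
# tests, rank correlation and ROC/AUC discrimination of DR severity from
# the spectrum parameters.

#' DR severity grades, mildest to most severe
#'
#' @return character vector of grade levels.
#' @export
dr_grades <- function() {
  c("nondiabetic", "no_apparent", "mild_npdr", "moderate_npdr",
    "severe_npdr", "pdr")
}

#' Binary grouping schemes over DR grades
#'
#' Deterministic mappings from grade to case/control status used throughout
#' the cohort analyses. Grades not involved in a scheme map to NA and are
#' excluded from that comparison.
#'
#' * `diabetic`: any diabetic eye vs nondiabetic.
#' * `any_dr`: DR (mild NPDR or worse) vs no apparent retinopathy.
#' * `referable`: moderate NPDR or worse vs mild NPDR / no apparent
#'   retinopathy ("referable DR").
#' * `severe_pdr`: severe NPDR or PDR vs milder diabetic grades.
#' * `pdr_vs_npdr`: PDR vs any NPDR.
#'
#' @param grades character vector of grades (see [dr_grades()]).
#' @param scheme one of the scheme names above.
#' @return logical vector: TRUE = case, FALSE = control, NA = excluded.
#' @export
grade_grouping <- function(grades, scheme = c("diabetic", "any_dr", "referable",
                                              "severe_pdr", "pdr_vs_npdr")) {
  scheme <- match.arg(scheme)
  g <- match(grades, dr_grades())
  if (anyNA(g)) stop("invalid grade value(s): ",
                     paste(unique(grades[is.na(g)]), collapse = ", "))
  switch(scheme,
         diabetic = g >= 2,
         any_dr = ifelse(g == 1, NA, g >= 3),
         referable = ifelse(g == 1, NA, g >= 4),
         severe_pdr = ifelse(g == 1, NA, g >= 5),
         pdr_vs_npdr = ifelse(g <= 2, NA, g == 6))
}

#' Empirical ROC curve and AUC
#'
#' Threshold-sweep ROC with trapezoidal AUC (ties credited 0.5, so the AUC
#' equals the normalized Mann-Whitney U statistic exactly). Standard error
#' and 95% CI by the Hanley-McNeil distribution-free formula. The
#' orientation argument states which direction of the score indicates
#' disease; scores with `orientation = "lower"` are negated internally so
#' that higher oriented score = disease.
#'
#' @param scores numeric scores, one per eye.
#' @param labels logical or 0/1; TRUE = diseased.
#' @param orientation `"higher"` (default) or `"lower"`: direction of the
#'   score that indicates disease.
#' @return object of class `roc_result`: list with `auc`, `se`, `ci`
#'   (95%), `points` (data.frame of FPR, TPR), `orientation`, `n_case`,
#'   `n_control`.
#' @export
roc_auc <- function(scores, labels, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be non-empty")
  s <- if (orientation == "lower") -scores else scores
  ord <- order(s, decreasing = TRUE)
  lab <- labels[ord]
  sv <- s[ord]
  # cumulative counts at each distinct threshold
  grp <- cumsum(!duplicated(sv))
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * stats::qnorm(0.975) * se))
  structure(list(auc = auc, se = se, ci = ci,
                 points = data.frame(fpr = fpr, tpr = tpr),
                 orientation = orientation, n_case = n1, n_control = n0),
            class = "roc_result")
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p value by summing, over the margin-fixed hypergeometric
#' support, the probabilities of all tables no more likely than the observed
#' one (the minimum-likelihood convention). Also reports the sample odds
#' ratio ad/bc, row percentages, and (optionally) the chi-square p value.
#'
#' @param counts 2 x 2 matrix of non-negative integer counts (rows =
#'   groups, columns = outcome present/absent).
#' @param chisq also compute the uncorrected chi-square p value.
#' @return object of class `contingency_result`: list with `table`,
#'   `odds_ratio`, `p_value`, `row_pct` (percentage of the first column in
#'   each row), and `p_chisq`.
#' @export
fisher_exact_2x2 <- function(counts, chisq = TRUE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be a 2 x 2 matrix")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  a <- counts[1, 1]; b <- counts[1, 2]; c_ <- counts[2, 1]; d <- counts[2, 2]
  m <- a + b          # row 1 total
  n <- c_ + d         # row 2 total
  k <- a + c_         # column 1 total
  if (m + n == 0L) stop("empty table")
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  orat <- if (b * c_ > 0) (a * d) / (b * c_) else
    if (a * d > 0) Inf else NaN
  p_chi <- NA_real_
  if (chisq && all(rowSums(counts) > 0) && all(colSums(counts) > 0))
    p_chi <- suppressWarnings(stats::chisq.test(counts, correct = FALSE)$p.value)
  structure(list(table = counts, odds_ratio = orat, p_value = p,
                 row_pct = 100 * counts[, 1] / rowSums(counts),
                 p_chisq = p_chi),
            class = "contingency_result")
}

#' Kruskal-Wallis omnibus test with pairwise Mann-Whitney comparisons
#'
#' Tie-corrected Kruskal-Wallis H across all groups, followed by two-sided
#' pairwise Mann-Whitney U tests (midranks; exact for small tie-free
#' samples) with Bonferroni adjustment over the number of pairs actually
#' compared. Group medians and IQRs are reported in the clinical
#' median (IQR) convention.
#'
#' @param groups named list of numeric vectors (>= 2 non-empty groups).
#' @return list with `omnibus` (statistic, df, p), `pairwise` (data.frame:
#'   group1, group2, statistic, p_raw, p_adj), `summary` (data.frame:
#'   group, n, median, q1, q3).
#' @export
kruskal_pairwise <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (any(!vapply(groups, length, integer(1)))) stop("each group must be non-empty")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  kw <- stats::kruskal.test(x, g)
  pairs <- utils::combn(names(groups), 2L)
  npair <- ncol(pairs)
  pw <- lapply(seq_len(npair), function(i) {
    a <- groups[[pairs[1, i]]]
    b <- groups[[pairs[2, i]]]
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               statistic = unname(wt$statistic), p_raw = wt$p.value)
  })
  pw <- do.call(rbind, pw)
  pw$p_adj <- pmin(1, pw$p_raw * npair)
  qs <- t(vapply(groups, function(v)
    stats::quantile(v, c(0.5, 0.25, 0.75), names = FALSE, type = 7), numeric(3)))
  list(omnibus = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value),
       pairwise = pw,
       summary = data.frame(group = names(groups),
                            n = vapply(groups, length, integer(1)),
                            median = qs[, 1], q1 = qs[, 2], q3 = qs[, 3],
                            row.names = NULL))
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with a two-sided p value from the
#' t approximation. Constant input yields a missing coefficient with a
#' warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    warning("constant input: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Full severity report over a cohort of eye spectra
#'
#' For each spectrum parameter: median (IQR) per grade with Kruskal-Wallis
#' and Bonferroni-adjusted pairwise comparisons (when >= 2 grades are
#' present), and for each binary grouping scheme an ROC/AUC analysis.
#' Orientation is declared per parameter: the total space count falls with
#' disease (`"lower"`), all other parameters rise (`"higher"`). Groupings
#' with an empty class are skipped with a warning.
#'
#' @param cohort data.frame of eye spectrum rows (from [summarize_eye()])
#'   with a valid `grade` column.
#' @param parameters character vector of cohort columns to analyze.
#' @param schemes grouping schemes (see [grade_grouping()]).
#' @return object of class `severity_report`: list with `medians`, `tests`,
#'   `roc` (nested list `roc[[parameter]][[scheme]]`).
#' @export
severity_report <- function(cohort,
                            parameters = intersect(
                              c("total_count", "mean_area_mm2",
                                "mean_perimeter_mm", "mean_min_diam_mm",
                                "mean_max_diam_mm", "count_area_gt_0.03",
                                "count_ap_gt_0.025"), names(cohort)),
                            schemes = c("diabetic", "any_dr", "referable",
                                        "severe_pdr", "pdr_vs_npdr")) {
  stopifnot(is.data.frame(cohort), "grade" %in% names(cohort))
  grades_present <- intersect(dr_grades(), unique(cohort$grade))
  med_rows <- list()
  tests <- list()
  roc <- list()
  for (par in parameters) {
    v <- cohort[[par]]
    by_grade <- split(v, factor(cohort$grade, levels = grades_present))
    qs <- t(vapply(by_grade, function(g)
      stats::quantile(g, c(0.5, 0.25, 0.75), names = FALSE, na.rm = TRUE),
      numeric(3)))
    med_rows[[par]] <- data.frame(parameter = par, grade = grades_present,
                                  n = vapply(by_grade, length, integer(1)),
                                  median = qs[, 1], q1 = qs[, 2], q3 = qs[, 3],
                                  row.names = NULL)
    if (length(grades_present) >= 2L)
      tests[[par]] <- kruskal_pairwise(by_grade)
    orientation <- if (par == "total_count") "lower" else "higher"
    roc[[par]] <- list()
    for (sc in schemes) {
      cs <- grade_grouping(cohort$grade, sc)
      use <- !is.na(cs) & !is.na(v)
      if (sum(cs[use]) == 0L || sum(!cs[use]) == 0L) {
        warning(sprintf("scheme '%s': empty class for parameter '%s'; ROC skipped",
                        sc, par))
        next
      }
      roc[[par]][[sc]] <- roc_auc(v[use], cs[use], orientation)
    }
  }
  structure(list(medians = do.call(rbind, med_rows),
                 tests = tests, roc = roc,
                 parameters = parameters, schemes = schemes),
            class = "severity_report")
}

#' Contingency analysis of eyes with at least one high-ratio space
#'
#' Dichotomizes each eye by whether it carries one or more intercapillary
#' spaces meeting a count criterion (by default: area/perimeter ratio above
#' 0.025), crosses that with a binary severity grouping, and applies
#' Fisher's exact test.
#'
#' @param cohort data.frame of eye spectrum rows with a `grade` column.
#' @param scheme grouping scheme (see [grade_grouping()]).
#' @param column cohort column holding the per-eye criterion count.
#' @return a `contingency_result` (rows: case group then control group;
#'   columns: criterion met / not met).
#' @export
high_ratio_contingency <- function(cohort, scheme = "severe_pdr",
                                   column = "count_ap_gt_0.025") {
  stopifnot(column %in% names(cohort))
  cs <- grade_grouping(cohort$grade, scheme)
  use <- !is.na(cs)
  met <- cohort[[column]][use] >= 1L
  cs <- cs[use]
  tab <- matrix(c(sum(cs & met), sum(cs & !met),
                  sum(!cs & met), sum(!cs & !met)),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("case", "control"),
                                c("criterion_met", "criterion_not_met")))
  fisher_exact_2x2(tab)
}
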