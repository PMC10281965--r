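#' Median and interquartile range
#'
#' Linear-interpolation quantiles (R's type-7 convention; reported
#' median/IQR values depend on this choice, which is fixed and documented).
#'
#' @param values Non-empty numeric vector.
#' @return List `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  if (length(values) == 0) stop_validation("empty input")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  list(median = q[1], q1 = q[2], q3 = q[3])
}

#' Mann-Whitney U test
#'
#' `U = min(U_a, U_b)` from midrank sums. The two-sided p-value is exact
#' (network enumeration) when `n_a + n_b <= 12` and the pooled sample is
#' tie-free, otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b Non-empty numeric vectors (the two groups).
#' @return List `U`, `p`, `exact` (logical).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop_validation("empty group")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ub <- na * nb - ua
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (na + nb) <= 12 && !ties
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  list(U = min(ua, ub), p = min(p, 1), exact = exact)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction by default (the variant is explicit
#' because a reported p-value cannot adjudicate it); set `correct = TRUE`
#' for the Yates-corrected version. All expected counts must be positive.
#'
#' @param table 2x2 matrix of counts.
#' @param correct Apply Yates continuity correction?
#' @return List `statistic`, `p`, `df`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stop_validation("table must be 2x2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_validation("zero marginal in 2x2 table")
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Two-sample Student's t-test (pooled variance)
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @return List `statistic`, `p`, `df` (`n_a + n_b - 2`).
#' @export
student_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop_validation("both groups need >= 2 values")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Group-comparison table for the three features
#'
#' For each shape and feature (DT, AP, SP): group medians and IQR bounds
#' plus the Mann-Whitney two-sided p-value, flagged at the 0.05 level.
#' p-values are reported raw, without multiple-testing correction, matching
#' the usual presentation of this screening literature.
#'
#' @param features Labeled feature table ([extract_features()]).
#' @param alpha Significance level for the flag.
#' @return data.frame with one row per shape x feature: `shape`, `feature`,
#'   `noncm_median`, `noncm_q1`, `noncm_q3`, `cm_median`, `cm_q1`,
#'   `cm_q3`, `p_value`, `significant`.
#' @export
comparison_table <- function(features, alpha = 0.05) {
  if (!all(c("group", "shape") %in% names(features)) ||
      any(is.na(features$group)))
    stop_validation("labeled feature table required")
  shapes <- intersect(SHAPES, unique(features$shape))
  rows <- list()
  for (s in shapes) for (f in c("DT", "AP", "SP")) {
    v <- features[features$shape == s, ]
    x0 <- v[[f]][v$group == "nonCM"]
    x1 <- v[[f]][v$group == "CM"]
    m0 <- median_iqr(x0); m1 <- median_iqr(x1)
    mw <- mann_whitney_u(x0, x1)
    rows[[length(rows) + 1]] <- data.frame(
      shape = s, feature = f,
      noncm_median = m0$median, noncm_q1 = m0$q1, noncm_q3 = m0$q3,
      cm_median = m1$median, cm_q1 = m1$q1, cm_q3 = m1$q3,
      p_value = mw$p, significant = mw$p < alpha,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Demographic comparison of a cohort's two groups
#'
#' Age is compared with the pooled two-sample t-test, sex with the
#' chi-square test on the 2x2 sex-by-group table (no continuity
#' correction), mirroring the usual participant-characteristics table.
#'
#' @param participants Participant data.frame with `group`, `age`, `sex`.
#' @return data.frame with one row per variable: summaries per group,
#'   `test`, `p_value`.
#' @export
demographics_table <- function(participants) {
  g0 <- participants[participants$group == "nonCM", ]
  g1 <- participants[participants$group == "CM", ]
  a0 <- median_iqr(g0$age); a1 <- median_iqr(g1$age)
  tt <- student_t(g0$age, g1$age)
  tab <- rbind(table(factor(g0$sex, c("F", "M"))),
               table(factor(g1$sex, c("F", "M"))))
  cs <- chi_square_2x2(tab)
  data.frame(
    variable = c("n", "age_median_iqr", "sex_female"),
    noncm = c(nrow(g0),
              sprintf("%g (%g-%g)", a0$median, a0$q1, a0$q3),
              sprintf("%d (%.0f%%)", sum(g0$sex == "F"),
                      100 * mean(g0$sex == "F"))),
    cm = c(nrow(g1),
           sprintf("%g (%g-%g)", a1$median, a1$q1, a1$q3),
           sprintf("%d (%.0f%%)", sum(g1$sex == "F"),
                   100 * mean(g1$sex == "F"))),
    test = c(NA, "Student t", "chi-square"),
    p_value = c(NA, tt$p, cs$p),
    stringsAsFactors = FALSE)
}
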