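# Statistical engine for the stratified analyses.
#
# Thin, validated fronts over the standard tests: Wilcoxon signed rank for
# the per-stratum angle distributions, chi-squared (2x2 Yates-corrected and
# r x c uncorrected) for enrichment and composition tables, Pearson
# correlation and the two-sample t-test.  Significance marks follow the
# figure convention: "**" for p < 0.01, "*" for 0.01 <= p < 0.05, blank
# otherwise.

#' Wilcoxon signed-rank test
#'
#' One-sample signed-rank test of symmetric location `mu`.  Zeros are
#' dropped (the signed-rank convention) and tied absolute values get
#' averaged ranks.  The exact null distribution is used for n <= 25
#' without ties; otherwise the normal approximation with continuity
#' correction.
#'
#' @param x numeric values.
#' @param mu hypothesised centre (default 0).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return list with `statistic` (V), `p_value`, `n_used` (non-zero
#'   differences) and `exact` (logical).
#' @examples
#' wilcoxon_signed_rank(1:6, alternative = "greater")$p_value  # 1/64
#' @export
wilcoxon_signed_rank <- function(x, mu = 0,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  d <- x[!is.na(x)] - mu
  d <- d[d != 0]
  if (!length(d))
    stop("all values equal mu; no information", call. = FALSE)
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  res <- suppressWarnings(
    stats::wilcox.test(d, alternative = alternative, exact = exact,
                       correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       n_used = length(d), exact = exact)
}

#' Stratified signed-rank tests on response angles
#'
#' Splits an angle table into strata and tests each stratum's angles
#' against zero (two-sided), reporting the direction from the sign of the
#' median.  Strata smaller than `min_n` are reported with their n but
#' never marked; strata whose angles are identically zero are reported as
#' uninformative (`p_value = NA`).
#'
#' @param pairs data frame from [compute_alpha()] (needs column `alpha`).
#' @param by stratum key columns (default metric, sex, BP history and
#'   age group).
#' @param min_n minimum stratum size for a significance mark (default 5).
#' @return data frame with one row per non-empty stratum: the key columns,
#'   `n`, `median_alpha`, `statistic`, `p_value`, `mark` and `direction`.
#' @export
test_strata <- function(pairs, by = c("metric", "sex", "bp", "age_group"),
                        min_n = 5L) {
  stopifnot(all(by %in% names(pairs)), "alpha" %in% names(pairs))
  groups <- split(seq_len(nrow(pairs)), pairs[by], drop = TRUE)
  rows <- lapply(groups, function(idx) {
    a <- pairs$alpha[idx]
    key <- pairs[idx[1L], by, drop = FALSE]
    med <- stats::median(a)
    if (all(a == 0)) {
      stat <- NA_real_; p <- NA_real_
    } else {
      w <- wilcoxon_signed_rank(a, alternative = "two.sided")
      stat <- w$statistic; p <- w$p_value
    }
    mark <- ""
    if (!is.na(p) && length(a) >= min_n)
      mark <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
    direction <- if (is.na(p) || med == 0) "none"
                 else if (med > 0) "positive" else "negative"
    cbind(key, data.frame(n = length(a), median_alpha = med,
                          statistic = stat, p_value = p, mark = mark,
                          direction = direction,
                          stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chi-squared test on a 2x2 table
#'
#' Pearson chi-squared with Yates continuity correction by default (the
#' corrected statistic is `n(|ad - bc| - n/2)^2` over the product of the
#' marginals, clamped at 0), 1 degree of freedom.
#'
#' @param a,b first row (e.g. cluster 1: missense, non-missense).
#' @param c,d second row.
#' @param continuity apply Yates correction (default TRUE).
#' @return list with `statistic`, `df`, `p_value` and the 2x2 `table`.
#' @examples
#' chi2_2x2(33, 6, 29, 22)$p_value  # about 0.0096
#' @export
chi2_2x2 <- function(a, b, c, d, continuity = TRUE) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(m < 0)) stop("cells must be non-negative", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero marginal in 2x2 table", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(m, correct = continuity))
  list(statistic = unname(res$statistic), df = 1L,
       p_value = res$p.value, table = m)
}

#' Pearson chi-squared test on an r x c table
#'
#' Uncorrected Pearson statistic with (r-1)(c-1) degrees of freedom.
#'
#' @param tab numeric matrix, r, c >= 2, no zero marginal.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi2_rxc <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("table must be at least 2x2", call. = FALSE)
  if (any(tab < 0)) stop("cells must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in table", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance", call. = FALSE)
  stats::cor(x, y)
}

#' Two-sample t-test (unpaired, two-tailed)
#'
#' Welch's unequal-variance form by default; set `var_equal = TRUE` for
#' the pooled-variance Student form.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param var_equal pool variances (default FALSE).
#' @return list with `statistic` (t), `df`, `p_value`.
#' @export
t_test_two_sample <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs n >= 2", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("degenerate variance in both groups", call. = FALSE)
  res <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}
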