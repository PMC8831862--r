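test_that("signed-rank test matches its exact and approximate oracles", {
  # six positive values, one-sided: p = 2^-6
  r <- wilcoxon_signed_rank(c(0.2, 0.5, 1.1, 2.3, 3.1, 4.0),
                            alternative = "greater")
  expect_equal(r$p_value, 1 / 64)
  expect_true(r$exact)

  # perfectly symmetric sample, two-sided
  r <- wilcoxon_signed_rank(c(-3, 3, -1.5, 1.5, -0.7, 0.7))
  expect_equal(r$p_value, 1)

  # n = 40: normal approximation with continuity correction vs oracle
  set.seed(37)
  for (i in 1:10) {
    x <- rnorm(40, mean = 0.2)
    for (alt in c("two.sided", "greater", "less")) {
      got <- wilcoxon_signed_rank(x, alternative = alt)
      ora <- wilcoxon_approx_oracle(x, alternative = alt)
      expect_false(got$exact)
      expect_equal(got$statistic, ora$statistic)
      expect_equal(got$p_value, ora$p_value, tolerance = 1e-8)
    }
  }
  expect_error(wilcoxon_signed_rank(rep(2, 5), mu = 2), "no information")
})

test_that("2x2 chi-squared matches the closed forms with and without Yates", {
  for (i in 1:500) {
    set.seed(i)
    cells <- rpois(4, 12) + 1
    for (cont in c(TRUE, FALSE)) {
      got <- chi2_2x2(cells[1], cells[2], cells[3], cells[4],
                      continuity = cont)
      ora <- chi2_2x2_oracle(cells[1], cells[2], cells[3], cells[4],
                             continuity = cont)
      expect_equal(got$statistic, ora$statistic, tolerance = 1e-9)
      expect_equal(got$p_value, ora$p_value, tolerance = 1e-9)
    }
  }
  r <- chi2_2x2(10, 10, 10, 10)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(chi2_2x2(0, 0, 5, 5), "marginal")
})

test_that("r x c chi-squared matches the Pearson formula", {
  r <- chi2_rxc(rbind(c(10, 20, 30), c(1, 2, 3)))   # proportional rows
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)

  r <- chi2_rxc(rbind(c(33, 6), c(29, 22)))
  expect_equal(r$statistic, 7.942, tolerance = 1e-3)

  set.seed(43)
  for (i in 1:100) {
    tab <- matrix(rpois(8, 9) + 1, 2, 4)
    got <- chi2_rxc(tab)
    ora <- chi2_rxc_oracle(tab)
    expect_equal(got$statistic, ora$statistic, tolerance = 1e-9)
    expect_equal(got$df, ora$df)
    expect_equal(got$p_value, ora$p_value, tolerance = 1e-9)
  }
  expect_error(chi2_rxc(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("correlation and t-test fronts behave at their closed forms", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(2, 5)), "variance")
  expect_error(pearson_r(1:2, 1:2), "length")

  set.seed(47)
  z <- matrix(rnorm(1000), ncol = 2)
  z[, 2] <- 0.9 * z[, 1] + sqrt(1 - 0.81) * z[, 2]
  expect_equal(pearson_r(z[, 1], z[, 2]), 0.9, tolerance = 0.04)

  g <- rnorm(20)
  r <- t_test_two_sample(g, g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r <- t_test_two_sample(g, g + 100)
  expect_lt(r$p_value, 1e-12)
  x <- rnorm(15); y <- rnorm(18, 0.5, 2)
  got <- t_test_two_sample(x, y)
  ora <- welch_oracle(x, y)
  expect_equal(got$statistic, ora$statistic, tolerance = 1e-9)
  expect_equal(got$df, ora$df, tolerance = 1e-9)
  expect_equal(got$p_value, ora$p_value, tolerance = 1e-9)
  expect_error(t_test_two_sample(rep(1, 3), rep(1, 3)), "degenerate")
})

test_that("stratum tests mark, direct and gate on size correctly", {
  set.seed(53)
  pairs <- data.frame(
    metric = rep(c("spine_bmd", "height"), each = 40),
    sex = "male", bp = TRUE,
    age_group = rep(rep(c("10-15", "15-20"), each = 20), 2),
    alpha = c(abs(rnorm(20, 0.4, 0.1)),        # strongly positive
              rnorm(20, 0, 0.02),              # null
              -abs(rnorm(20, 0.3, 0.1)),       # strongly negative
              rnorm(20, 0, 0.02)))
  res <- test_strata(pairs)
  get <- function(m, g) res[res$metric == m & res$age_group == g, ]
  expect_equal(get("spine_bmd", "10-15")$mark, "**")
  expect_equal(get("spine_bmd", "10-15")$direction, "positive")
  expect_equal(get("height", "10-15")$mark, "**")
  expect_equal(get("height", "10-15")$direction, "negative")
  expect_equal(get("spine_bmd", "15-20")$mark, "")

  # permutation invariance
  perm <- pairs[sample(nrow(pairs)), ]
  res2 <- test_strata(perm)
  key <- function(d) paste(d$metric, d$age_group)
  expect_equal(res$p_value[order(key(res))],
               res2$p_value[order(key(res2))])

  # identically-zero stratum is uninformative, never marked
  zero <- data.frame(metric = "height", sex = "f", bp = FALSE,
                     age_group = "5-10", alpha = rep(0, 10))
  rz <- test_strata(zero)
  expect_true(is.na(rz$p_value))
  expect_equal(rz$mark, "")

  # small strata are reported but not marked
  tiny <- data.frame(metric = "height", sex = "f", bp = FALSE,
                     age_group = "5-10", alpha = c(0.5, 0.6, 0.7))
  rt <- test_strata(tiny)
  expect_equal(rt$n, 3)
  expect_equal(rt$mark, "")
})
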