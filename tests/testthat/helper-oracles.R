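# Independent oracles and small fixture builders shared across tests.
# Oracles are written from the textbook definitions and never call the
# package functions they check.

# Local polynomial regression at query points: tricube weights over the
# floor(n * span) nearest neighbours, weighted least squares of the given
# degree re-solved at each query point.
loess_oracle <- function(x, y, x0, span = 0.75, degree = 2) {
  n <- length(x)
  q <- floor(n * span)
  vapply(x0, function(z) {
    d <- abs(x - z)
    h <- sort(d)[q]
    w <- pmax(0, 1 - (d / h)^3)^3
    X <- outer(x - z, 0:degree, "^")
    stats::lm.wfit(X, y, w)$coefficients[1]
  }, numeric(1))
}

# Complete-linkage agglomeration by exhaustive enumeration: at each step
# scan every cluster pair for the minimal maximum inter-point distance.
# Returns merge heights in order and the partition when `stop_at` clusters
# remain; flags whether any step had a tied minimum.
complete_linkage_bruteforce <- function(m, stop_at = 1L) {
  d <- as.matrix(stats::dist(m))
  cl <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  tie_free <- TRUE
  partition <- NULL
  while (length(cl) > 1L) {
    if (length(cl) == stop_at) {
      partition <- integer(nrow(m))
      for (g in seq_along(cl)) partition[cl[[g]]] <- g
    }
    best <- NULL; hbest <- Inf; nmin <- 0L
    for (i in seq_len(length(cl) - 1L)) for (j in seq(i + 1L, length(cl))) {
      h <- max(d[cl[[i]], cl[[j]]])
      if (abs(h - hbest) < 1e-12) nmin <- nmin + 1L
      else if (h < hbest) { hbest <- h; best <- c(i, j); nmin <- 1L }
    }
    if (nmin > 1L) tie_free <- FALSE
    heights <- c(heights, hbest)
    cl[[best[1L]]] <- c(cl[[best[1L]]], cl[[best[2L]]])
    cl[[best[2L]]] <- NULL
  }
  if (stop_at == 1L) {
    partition <- rep(1L, nrow(m))
  }
  list(heights = heights, partition = partition, tie_free = tie_free)
}

# Pearson chi-squared on a 2x2, from the closed forms.
chi2_2x2_oracle <- function(a, b, c, d, continuity = TRUE) {
  n <- a + b + c + d
  num <- abs(a * d - b * c)
  if (continuity) num <- max(0, num - n / 2)
  stat <- n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Pearson chi-squared on an r x c table from sum((O-E)^2/E).
chi2_rxc_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Large-sample signed-rank test with continuity correction and tie
# correction, from the normal-approximation formulas.
wilcoxon_approx_oracle <- function(x, mu = 0,
                                   alternative = "two.sided") {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  m <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- V - m
  cc <- switch(alternative, two.sided = sign(z) * 0.5, greater = 0.5,
               less = -0.5)
  z <- (z - cc) / sqrt(sig2)
  p <- switch(alternative,
              two.sided = 2 * min(stats::pnorm(z),
                                  stats::pnorm(z, lower.tail = FALSE)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  list(statistic = V, p_value = min(1, p))
}

# Welch two-sample t from the closed form.
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df))
}

# A minimal measurement frame, one metric, defaults chosen for readability
# in tests.
make_meas <- function(patient_id = "P1", sex = "male", group = "non-OI",
                      age, value, metric = "height", bp_treated = FALSE,
                      visit_key = sprintf("V%02d", seq_along(age))) {
  data.frame(patient_id = patient_id, sex = sex, group = group, age = age,
             metric = metric, value = value, bp_treated = bp_treated,
             visit_key = visit_key, stringsAsFactors = FALSE)
}

# The tie-free 6 x 10 binary matrix used for the linkage oracle test
# (searched offline for unique minima at every agglomeration step).
linkage_fixture <- function() {
  set.seed(42)
  m <- matrix(stats::rbinom(60, 1, 0.5), 6, 10)
  rownames(m) <- paste0("P", 1:6)
  colnames(m) <- paste0("t", 1:10)
  m
}
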