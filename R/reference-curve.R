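# Normal-growth reference curves.
#
# The non-OI control records for one metric and sex are smoothed with LOESS
# (locally weighted polynomial regression, tricube weights, Gaussian
# family) to give the normal growth curve f(age).  Fits use the direct
# surface so the local polynomial is re-solved at every query age, which
# makes the expected slope k = [f(t2) - f(t1)]/(t2 - t1) well defined for
# arbitrary age pairs inside the training domain.  Extrapolation outside
# the domain is refused.

#' Fit a LOESS normal-growth reference curve
#'
#' @param records measurement data frame (typically selected non-OI
#'   controls); filtered to `metric` and `sex` when given.
#' @param metric,sex optional filters; required if `records` mixes several.
#' @param span fraction of points in each local neighbourhood, in (0, 1\]
#'   (default 0.75).
#' @param degree local polynomial degree, 0, 1 or 2 (default 2).
#' @return object of class `ref_curve` with the fitted model, its training
#'   `domain` (age range) and parameters.
#' @seealso [predict.ref_curve()], [ref_scale()]
#' @export
fit_reference <- function(records, metric = NULL, sex = NULL,
                          span = 0.75, degree = 2) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]", call. = FALSE)
  if (!degree %in% 0:2) stop("degree must be 0, 1 or 2", call. = FALSE)
  d <- records
  if (!is.null(metric)) d <- d[d$metric == metric, , drop = FALSE]
  if (!is.null(sex)) d <- d[d$sex == sex, , drop = FALSE]
  if (length(unique(d$metric)) > 1L || length(unique(d$sex)) > 1L)
    stop("records mix metrics or sexes; pass metric= and sex=",
         call. = FALSE)
  if (nrow(d) < max(10L, degree + 1L))
    stop("too few records to fit a reference curve (", nrow(d), ")",
         call. = FALSE)
  if (length(unique(d$age)) < 2L)
    stop("all training ages identical", call. = FALSE)
  fit <- stats::loess(value ~ age, data = d, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  structure(list(fit = fit, metric = unique(d$metric)[1L],
                 sex = unique(d$sex)[1L], span = span, degree = degree,
                 domain = range(d$age), n = nrow(d)),
            class = "ref_curve")
}

#' Evaluate a reference curve
#'
#' @param object a `ref_curve`.
#' @param age ages to evaluate, all within the training domain.
#' @param se if `TRUE`, return a list with `fit` and `se` (pointwise
#'   standard errors from the local regression operator).
#' @param ... ignored.
#' @return numeric fitted values, or a list when `se = TRUE`.
#' @export
predict.ref_curve <- function(object, age, se = FALSE, ...) {
  if (any(age < object$domain[1] | age > object$domain[2]))
    stop("age outside curve domain [", object$domain[1], ", ",
         object$domain[2], "]", call. = FALSE)
  p <- stats::predict(object$fit, newdata = data.frame(age = age), se = se)
  if (se) list(fit = as.numeric(p$fit), se = as.numeric(p$se.fit))
  else as.numeric(p)
}

#' @export
print.ref_curve <- function(x, ...) {
  cat("LOESS reference curve:", x$metric, "/", x$sex, "\n")
  cat(sprintf("  n = %d, span = %g, degree = %d, domain = [%.2f, %.2f]\n",
              x$n, x$span, x$degree, x$domain[1], x$domain[2]))
  cat(sprintf("  mean slope C = %.4g per year\n", ref_scale(x)))
  invisible(x)
}

#' @export
plot.ref_curve <- function(x, n_grid = 100, band = TRUE, ...) {
  ages <- seq(x$domain[1], x$domain[2], length.out = n_grid)
  p <- predict(x, ages, se = band)
  if (band) {
    graphics::plot(ages, p$fit, type = "l", xlab = "age (years)",
                   ylab = x$metric, main = paste(x$metric, x$sex), ...)
    graphics::lines(ages, p$fit + 2 * p$se, lty = 2)
    graphics::lines(ages, p$fit - 2 * p$se, lty = 2)
  } else {
    graphics::plot(ages, p, type = "l", xlab = "age (years)",
                   ylab = x$metric, main = paste(x$metric, x$sex), ...)
  }
  invisible(x)
}

#' Normalising scale of a reference curve
#'
#' The mean slope of the curve over its domain,
#' `C = (f(hi) - f(lo)) / (hi - lo)`.  Dividing a slope by C before taking
#' its arctangent makes response angles dimensionless and hence comparable
#' across metrics measured in different units (BMD vs height).
#'
#' @param curve a `ref_curve`.
#' @return positive scalar C; an error if the curve is flat or declining.
#' @export
ref_scale <- function(curve) {
  stopifnot(inherits(curve, "ref_curve"))
  ends <- predict(curve, curve$domain)
  C <- (ends[2] - ends[1]) / (curve$domain[2] - curve$domain[1])
  if (!is.finite(C) || C <= 0)
    stop("reference curve is flat or declining; no valid scale",
         call. = FALSE)
  C
}

#' Fit reference curves for every (metric, sex) present
#'
#' @param records control measurement data frame.
#' @param span,degree passed to [fit_reference()].
#' @return named list of `ref_curve` objects keyed `"metric.sex"`.
#' @export
fit_reference_set <- function(records, span = 0.75, degree = 2) {
  combos <- unique(records[c("metric", "sex")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    m <- combos$metric[i]; s <- combos$sex[i]
    out[[paste(m, s, sep = ".")]] <-
      fit_reference(records, metric = m, sex = s, span = span,
                    degree = degree)
  }
  out
}
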