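# Top-level treatment-response fit.
#
# Chains the whole growth analysis: deduplicate scans, select stratified
# non-OI controls, fit LOESS reference curves per metric and sex, build
# successive-reading pairs for the OI patients, compute response angles
# and run the stratified Wilcoxon tests.

#' Fit the bisphosphonate treatment-response analysis
#'
#' @param measurements measurement data frame mixing OI and non-OI records
#'   (see [read_measurements()]).
#' @param metrics metrics to analyse (default spine BMD and height, the
#'   two with interpretable treatment response).
#' @param oi_groups which OI groups contribute response pairs.
#' @param plan control-selection plan ([selection_plan()]).
#' @param span,degree LOESS parameters for the reference curves.
#' @param min_n minimum stratum size for a significance mark.
#' @return object of class `bp_response` with components `curves` (named
#'   list of `ref_curve`), `controls` (selected control records), `pairs`
#'   (angle table) and `strata` (per-stratum test results).
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_config(n_oi = 60, n_nonoi = 120, seed = 2))
#' fit <- bp_response(cohort$measurements)
#' summary(fit)
#' }
#' @export
bp_response <- function(measurements,
                        metrics = c("spine_bmd", "height"),
                        oi_groups = c("OI-COL1", "OI-nonCOL1"),
                        plan = selection_plan(), span = 0.75, degree = 2,
                        min_n = 5L) {
  d <- dedupe_max(measurements)
  d <- d[d$metric %in% metrics, , drop = FALSE]
  nonoi <- d[d$group == "non-OI", , drop = FALSE]
  oi <- d[d$group %in% oi_groups, , drop = FALSE]
  if (!nrow(nonoi)) stop("no non-OI control records", call. = FALSE)
  if (!nrow(oi)) stop("no OI records in the requested groups",
                      call. = FALSE)
  controls <- select_controls(nonoi, plan)
  curves <- fit_reference_set(controls, span = span, degree = degree)
  pairs <- make_pairs(oi, bin_width = plan$bin_width)
  pairs <- compute_alpha(pairs, curves)
  strata <- if (nrow(pairs)) test_strata(pairs, min_n = min_n) else NULL
  structure(list(curves = curves, controls = controls, pairs = pairs,
                 strata = strata, plan = plan, metrics = metrics,
                 call = match.call()),
            class = "bp_response")
}

#' @export
print.bp_response <- function(x, ...) {
  cat("Bisphosphonate treatment-response analysis\n")
  cat(sprintf("  %d control records, %d reference curves, %d pairs\n",
              nrow(x$controls), length(x$curves), nrow(x$pairs)))
  if (!is.null(x$strata)) {
    sig <- x$strata[x$strata$mark != "", , drop = FALSE]
    cat(sprintf("  %d strata tested, %d marked significant\n",
                nrow(x$strata), nrow(sig)))
    if (nrow(sig)) {
      for (i in seq_len(nrow(sig)))
        cat(sprintf("   %s %s/%s %s BP=%s 	 median alpha %+0.3f (n=%d, p=%.3g)\n",
                    sig$mark[i], sig$metric[i], sig$sex[i],
                    sig$age_group[i], sig$bp[i], sig$median_alpha[i],
                    sig$n[i], sig$p_value[i]))
    }
  }
  invisible(x)
}

#' @export
summary.bp_response <- function(object, ...) {
  s <- object$strata
  if (!is.null(s))
    s <- s[order(s$metric, s$sex, s$bp, s$age_group), ]
  rownames(s) <- NULL
  s
}

#' @export
plot.bp_response <- function(x, metric = x$metrics[1], ...) {
  p <- x$pairs[x$pairs$metric == metric, , drop = FALSE]
  if (!nrow(p)) stop("no pairs for metric ", metric, call. = FALSE)
  grp <- interaction(p$age_group, ifelse(p$bp, "BP", "noBP"), drop = TRUE)
  graphics::boxplot(p$alpha ~ grp, horizontal = TRUE, las = 1,
                    xlab = expression(alpha ~ "(radians)"),
                    main = paste("Response angles:", metric), ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
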