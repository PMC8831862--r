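# The normalised response-angle statistic.
#
# For two successive readings (t1, b1) -> (t2, b2) of one patient and
# metric, the actual growth slope is k' = (b2 - b1)/(t2 - t1) and the
# expected slope on the normal-growth curve is k = [f(t2) - f(t1)]/(t2 -
# t1).  The response angle is
#
#     alpha = atan(k'/C') - atan(k/C)
#
# with C' = C the mean slope of the reference curve (see ref_scale()), so
# alpha is dimensionless: positive when the patient grows faster than the
# reference population, negative when slower, zero on-curve.  Rescaling a
# metric's units rescales k, k' and C identically and leaves alpha
# unchanged, which is what makes BMD and height angles comparable.

#' Build successive-reading pairs
#'
#' From n deduplicated readings of one patient and metric, forms the n-1
#' consecutive-in-age pairs.  Each pair is dated at its age midpoint
#' `(t1 + t2)/2` and assigned the 5-year age bin of that midpoint; the
#' BP-history flag is TRUE when the patient reported prior bisphosphonate
#' treatment at or before the second reading.
#'
#' @param records deduplicated measurement data frame (any mix of patients
#'   and metrics).
#' @param bin_width age-bin width in years for the pair's age group.
#' @return data frame with one row per pair: `patient_id`, `metric`, `sex`,
#'   `group`, `bp`, `t1`, `t2`, `b1`, `b2`, `k_prime`, `age_group`.
#'   Patients with a single reading contribute no rows.  Tied ages within
#'   one patient and metric (which deduplication should have removed) are
#'   an error.
#' @export
make_pairs <- function(records, bin_width = 5) {
  cols <- c("patient_id", "metric", "sex", "group", "bp", "t1", "t2",
            "b1", "b2", "k_prime", "age_group")
  empty <- stats::setNames(
    data.frame(character(), character(), character(), character(),
               logical(), numeric(), numeric(), numeric(), numeric(),
               numeric(), character(), stringsAsFactors = FALSE), cols)
  if (nrow(records) < 2L) return(empty)
  parts <- split(records, list(records$patient_id, records$metric),
                 drop = TRUE)
  out <- lapply(parts, function(d) {
    if (nrow(d) < 2L) return(NULL)
    d <- d[order(d$age), , drop = FALSE]
    if (any(diff(d$age) == 0))
      stop("tied ages for patient ", d$patient_id[1L], " metric ",
           d$metric[1L], " after deduplication", call. = FALSE)
    i <- seq_len(nrow(d) - 1L)
    t1 <- d$age[i]; t2 <- d$age[i + 1L]
    bp2 <- cumsum(d$bp_treated) > 0     # treated at or before this reading
    data.frame(patient_id = d$patient_id[1L], metric = d$metric[1L],
               sex = d$sex[1L], group = d$group[1L],
               bp = bp2[i + 1L], t1 = t1, t2 = t2,
               b1 = d$value[i], b2 = d$value[i + 1L],
               k_prime = (d$value[i + 1L] - d$value[i]) / (t2 - t1),
               age_group = assign_age_bin((t1 + t2) / 2, bin_width),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Compute response angles for a pair table
#'
#' Evaluates the reference curve at each pair's endpoint ages, forms the
#' expected slope k and the angle `alpha = atan(k'/C') - atan(k/C)`.
#' Pairs whose endpoints fall outside the matching curve's domain are
#' dropped with a warning.  Pairs with no matching curve for their
#' (metric, sex) are dropped likewise.
#'
#' @param pairs data frame from [make_pairs()].
#' @param curves named list of `ref_curve` objects keyed `"metric.sex"`
#'   (see [fit_reference_set()]).
#' @param scales optional named numeric vector of C values keyed like
#'   `curves`; computed with [ref_scale()] when missing.  `C' = C`.
#' @return `pairs` with columns `k`, `C` and `alpha` (radians) added.
#' @export
compute_alpha <- function(pairs, curves, scales = NULL) {
  if (nrow(pairs) == 0L) {
    pairs$k <- numeric(0); pairs$C <- numeric(0); pairs$alpha <- numeric(0)
    return(pairs)
  }
  key <- paste(pairs$metric, pairs$sex, sep = ".")
  if (is.null(scales))
    scales <- vapply(curves, ref_scale, numeric(1))
  k <- C <- alpha <- rep(NA_real_, nrow(pairs))
  for (ky in unique(key)) {
    idx <- which(key == ky)
    cv <- curves[[ky]]
    if (is.null(cv)) {
      warning("no reference curve for ", ky, "; ", length(idx),
              " pair(s) dropped", call. = FALSE)
      next
    }
    ok <- pairs$t1[idx] >= cv$domain[1] & pairs$t2[idx] <= cv$domain[2]
    if (any(!ok))
      warning(sum(!ok), " pair(s) outside the ", ky,
              " curve domain dropped", call. = FALSE)
    idx <- idx[ok]
    if (!length(idx)) next
    f1 <- predict(cv, pairs$t1[idx])
    f2 <- predict(cv, pairs$t2[idx])
    kk <- (f2 - f1) / (pairs$t2[idx] - pairs$t1[idx])
    cc <- scales[[ky]]
    if (!is.finite(cc) || cc <= 0)
      stop("non-positive scale for ", ky, call. = FALSE)
    k[idx] <- kk
    C[idx] <- cc
    alpha[idx] <- atan(pairs$k_prime[idx] / cc) - atan(kk / cc)
  }
  pairs$k <- k; pairs$C <- C; pairs$alpha <- alpha
  pairs[!is.na(alpha), , drop = FALSE]
}

#' Angle from explicit slopes
#'
#' The bare statistic `atan(k_prime/C_prime) - atan(k/C)`, exposed for
#' closed-form checks; all arguments vectorised.
#'
#' @param k_prime actual slope; `k` expected slope; `C`, `C_prime` positive
#'   normalising scales (`C_prime` defaults to `C`).
#' @return angle in radians, in (-pi, pi).
#' @examples
#' response_angle(k_prime = 1, k = 0, C = 1)  # pi/4
#' @export
response_angle <- function(k_prime, k, C, C_prime = C) {
  if (any(C <= 0) || any(C_prime <= 0))
    stop("scales must be positive", call. = FALSE)
  atan(k_prime / C_prime) - atan(k / C)
}
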