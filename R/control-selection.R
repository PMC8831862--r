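# Age- and sex-stratified selection of non-OI control records.
#
# Hospital BMD archives are strongly age-skewed relative to a paediatric OI
# cohort: controls under 20 are scarce while adult records number in the
# tens of thousands.  The selection procedure keeps every control record
# below an age cutoff and caps each (5-year bin x sex x metric) cell above
# the cutoff at a fixed quota, derived from the control:case ratio observed
# in the last well-populated juvenile bin.

#' Assign ages to 5-year bins
#'
#' Bins are half-open `[lo, hi)` starting at 0, labelled `"0-5"`, `"5-10"`,
#' ..., so every age maps to exactly one bin; ages at or above `max_age`
#' fall into a final open-ended bin labelled `"<max_age>+"`.
#'
#' @param age numeric vector of ages in years (>= 0).
#' @param bin_width bin width in years (default 5).
#' @param max_age lower edge of the open-ended final bin (default 40).
#' @return character vector of bin labels.
#' @examples
#' assign_age_bin(c(0, 5, 17.3))  # "0-5" "5-10" "15-20"
#' @export
assign_age_bin <- function(age, bin_width = 5, max_age = 40) {
  if (any(is.na(age)) || any(age < 0))
    stop("age must be non-negative and non-missing", call. = FALSE)
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  lo <- floor(age / bin_width) * bin_width
  lab <- paste0(lo, "-", lo + bin_width)
  lab[age >= max_age] <- paste0(max_age, "+")
  lab
}

#' Ordered bin labels up to and including the open-ended bin
#' @inheritParams assign_age_bin
#' @return character vector of labels in increasing age order.
#' @export
age_bin_levels <- function(bin_width = 5, max_age = 40) {
  lo <- seq(0, max_age - bin_width, by = bin_width)
  c(paste0(lo, "-", lo + bin_width), paste0(max_age, "+"))
}

#' Control-selection plan
#'
#' Bundles the parameters of the stratified control selection: the age bin
#' width, the cutoff below which all control records are kept, per-metric
#' quotas for bins above the cutoff, the bin whose control:case ratio
#' motivates the quotas, and a sampling seed.
#'
#' Default quotas follow the cohort-derived values of 12 hip-BMD and 26
#' spine-BMD records per bin; height and weight accompany spine scans and
#' share the spine quota.
#'
#' @param bin_width years per age bin (default 5).
#' @param age_cutoff age below which all controls are kept; must be a
#'   multiple of `bin_width` (default 20).
#' @param quotas named integer vector, per-metric records to sample per
#'   (bin, sex) cell above the cutoff.
#' @param ratio_bin label of the bin used when deriving quotas from data.
#' @param seed integer seed making the random sampling reproducible.
#' @return object of class `selection_plan`.
#' @export
selection_plan <- function(bin_width = 5, age_cutoff = 20,
                           quotas = c(spine_bmd = 26, hip_bmd = 12,
                                      height = 26, weight = 26),
                           ratio_bin = "15-20", seed = 1L) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  if (any(quotas < 0)) stop("quotas must be >= 0", call. = FALSE)
  if (age_cutoff %% bin_width != 0)
    stop("age_cutoff must be a multiple of bin_width", call. = FALSE)
  structure(list(bin_width = bin_width, age_cutoff = age_cutoff,
                 quotas = quotas, ratio_bin = ratio_bin, seed = seed),
            class = "selection_plan")
}

#' Derive per-bin control quotas from a reference bin's ratio
#'
#' The control:case ratio observed in `ratio_bin` (e.g. roughly 1:4 in the
#' 15-20 group) is applied to the case count of every bin:
#' `quota = round(ratio * cases)`, floored at 0.
#'
#' @param oi_counts named vector of OI (case) record counts by bin.
#' @param nonoi_counts named vector of control record counts by bin.
#' @param ratio_bin name of the bin supplying the ratio; must have a
#'   positive OI count.
#' @return named numeric vector of quotas, one per bin of `oi_counts`.
#' @examples
#' derive_quota(c("15-20" = 40, "20-25" = 48), c("15-20" = 10), "15-20")
#' @export
derive_quota <- function(oi_counts, nonoi_counts, ratio_bin) {
  if (!ratio_bin %in% names(oi_counts) || is.na(oi_counts[ratio_bin]) ||
      oi_counts[ratio_bin] <= 0)
    stop("ratio_bin has no OI records", call. = FALSE)
  if (!ratio_bin %in% names(nonoi_counts))
    stop("ratio_bin missing from nonoi_counts", call. = FALSE)
  ratio <- nonoi_counts[[ratio_bin]] / oi_counts[[ratio_bin]]
  pmax(round(ratio * oi_counts), 0)
}

#' Select stratified non-OI control records
#'
#' Keeps every record with `age < age_cutoff`; for each (age bin, sex,
#' metric) cell at or above the cutoff, draws a uniform random sample
#' without replacement of size `min(quota, available)`.  Metrics without a
#' quota entry are kept in full.  Under-filled cells emit a warning.
#'
#' @param records data frame of deduplicated non-OI measurement records
#'   (see [read_measurements()] for the column dictionary).
#' @param plan a [selection_plan()].
#' @return subset of `records`; selection is reproducible from `plan$seed`.
#' @export
select_controls <- function(records, plan = selection_plan()) {
  stopifnot(inherits(plan, "selection_plan"))
  if (nrow(records) == 0L) return(records)
  bin <- assign_age_bin(records$age, plan$bin_width)
  below <- records$age < plan$age_cutoff
  keep <- which(below)
  above <- which(!below)
  if (length(above)) {
    cells <- split(above, list(bin[above], records$sex[above],
                               records$metric[above]), drop = TRUE)
    picked <- with_seed(plan$seed, {
      unlist(lapply(names(cells), function(nm) {
        idx <- cells[[nm]]
        metric <- records$metric[idx[1L]]
        q <- plan$quotas[metric]
        if (is.na(q)) return(idx)
        if (length(idx) < q)
          warning(sprintf("cell %s under-filled: %d available, quota %d",
                          nm, length(idx), q), call. = FALSE)
        if (length(idx) <= q) idx else sort(sample(idx, q))
      }), use.names = FALSE)
    })
    keep <- c(keep, picked)
  }
  records[sort(keep), , drop = FALSE]
}
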