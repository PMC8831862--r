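#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Percentage of a ratio, printed-style
#'
#' Computes `100 * num / den` rounded to `digits` decimal places, the form in
#' which cohort proportions are reported (e.g. 33/39 -> 84.6).
#'
#' @param num,den numerator and denominator (den > 0).
#' @param digits decimal places (default 1).
#' @return numeric percentage.
#' @examples
#' ratio_pct(33, 39)  # 84.6
#' @export
ratio_pct <- function(num, den, digits = 1) {
  if (any(den <= 0)) stop("den must be positive", call. = FALSE)
  round(100 * num / den, digits)
}

metric_levels <- c("height", "weight", "spine_bmd", "hip_bmd")
sex_levels <- c("female", "male")
group_levels <- c("OI-COL1", "OI-nonCOL1", "non-OI")
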