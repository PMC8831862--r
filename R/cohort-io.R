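# Tabular input/output for the cohort pipeline.
#
# Column dictionary for measurement tables (one row per scan of one metric):
#   patient_id  opaque string
#   sex         "female" | "male"
#   group       "OI-COL1" | "OI-nonCOL1" | "non-OI"
#   age         years at scan, >= 0
#   metric      "height" | "weight" | "spine_bmd" | "hip_bmd"
#   value       cm / kg / g/cm^2, > 0
#   bp_treated  prior-bisphosphonate flag, TRUE/FALSE (or 1/0)
#   visit_key   opaque scan-session identifier
# Files are tab-delimited for .tsv/.txt and comma-delimited for .csv, UTF-8,
# '.' decimal, header row mandatory.

measurement_columns <- c("patient_id", "sex", "group", "age", "metric",
                         "value", "bp_treated", "visit_key")

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read and validate a measurement table
#'
#' Reads a delimited measurement table, checks the schema, coerces types and
#' drops rows violating the record invariants (non-negative age, positive
#' value, recognised metric/sex/group) with row-numbered diagnostics.
#'
#' @param path file path; delimiter inferred from the extension (`.csv` =>
#'   comma, otherwise tab) unless `delim` is given.
#' @param delim optional field delimiter override.
#' @return data frame of validated records; the integer row numbers of any
#'   rejected rows are attached as attribute `"rejected"`.
#' @seealso [dedupe_max()], [write_measurements()]
#' @export
read_measurements <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = infer_delim(path, delim),
                          stringsAsFactors = FALSE)
  missing <- setdiff(measurement_columns, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[measurement_columns]
  df$patient_id <- as.character(df$patient_id)
  df$visit_key <- as.character(df$visit_key)
  df$age <- suppressWarnings(as.numeric(df$age))
  df$value <- suppressWarnings(as.numeric(df$value))
  df$bp_treated <- as.logical(df$bp_treated)
  bad <- which(is.na(df$age) | df$age < 0 |
               is.na(df$value) | df$value <= 0 |
               !(df$metric %in% metric_levels) |
               !(df$sex %in% sex_levels) |
               !(df$group %in% group_levels) |
               is.na(df$bp_treated))
  if (length(bad) == nrow(df))
    stop("all ", nrow(df), " rows failed validation", call. = FALSE)
  if (length(bad)) {
    message("rejected ", length(bad), " row(s): ",
            paste(utils::head(bad, 20), collapse = ", "))
    df <- df[-bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "rejected") <- bad
  df
}

#' Write a measurement table as TSV
#' @param records measurement data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  utils::write.table(records[measurement_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse repeat scans to their maximum
#'
#' When the same measurement was scanned more than once in a session, the
#' maximum reading is retained: for each (patient_id, metric, visit_key)
#' group exactly one record survives, the one with the largest value (ties
#' broken by original order).  Idempotent.
#'
#' @param records measurement data frame.
#' @return deduplicated data frame, original row order of survivors kept.
#' @export
dedupe_max <- function(records) {
  if (nrow(records) == 0L) return(records)
  key <- paste(records$patient_id, records$metric, records$visit_key,
               sep = "\r")
  ord <- order(key, -records$value)        # max first within key; stable ties
  sel <- sort(ord[!duplicated(key[ord])])  # survivors, original order
  out <- records[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Threshold filter for differential-expression tables
#'
#' Keeps rows with `adjusted_p < p_cut` and `|log2_fold_change| > lfc_cut`,
#' excluding genes whose group means are both below `min_mean`, and
#' partitions the survivors by fold-change sign.
#'
#' @param rows data frame with columns `gene_id`, `mean_group_a`,
#'   `mean_group_b`, `log2_fold_change`, `adjusted_p`.
#' @param p_cut adjusted-p threshold (strict, default 0.01).
#' @param lfc_cut absolute log2 fold-change threshold (strict, default 2).
#' @param min_mean minimum mean expression required in at least one group
#'   (default 1).
#' @return list with data frames `higher` (log2FC > 0) and `lower`.
#' @export
filter_degs <- function(rows, p_cut = 0.01, lfc_cut = 2, min_mean = 1) {
  stopifnot(p_cut > 0, lfc_cut > 0, min_mean > 0)
  keep <- rows$adjusted_p < p_cut &
    abs(rows$log2_fold_change) > lfc_cut &
    (rows$mean_group_a >= min_mean | rows$mean_group_b >= min_mean)
  kept <- rows[which(keep), , drop = FALSE]
  list(higher = kept[kept$log2_fold_change > 0, , drop = FALSE],
       lower = kept[kept$log2_fold_change < 0, , drop = FALSE])
}

#' Read a binary clinical-trait table
#'
#' First column must identify the patient; remaining columns are traits
#' coded 0/1 with missing entries allowed (empty or NA).
#'
#' @inheritParams read_measurements
#' @return data frame with column `patient_id` followed by 0/1/NA trait
#'   columns.
#' @export
read_traits <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = infer_delim(path, delim),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("trait table needs >= 2 trait columns", call. = FALSE)
  names(df)[1L] <- "patient_id"
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) stop("duplicate patient ids", call. = FALSE)
  for (j in seq(2L, ncol(df))) {
    v <- df[[j]]
    v[v %in% c("", "NA")] <- NA
    v <- suppressWarnings(as.integer(v))
    if (any(!v %in% c(0L, 1L, NA)))
      stop("trait column ", names(df)[j], " has entries outside {0,1,NA}",
           call. = FALSE)
    df[[j]] <- v
  }
  df
}

#' Read a curated variant table
#'
#' @inheritParams read_measurements
#' @return data frame with columns `patient_id` (optional in the file),
#'   `gene`, `cdna_hgvs`, `protein_hgvs`.
#' @export
read_variants <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = infer_delim(path, delim),
                          stringsAsFactors = FALSE)
  need <- c("gene", "cdna_hgvs")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(df$protein_hgvs)) df$protein_hgvs <- NA_character_
  df
}
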