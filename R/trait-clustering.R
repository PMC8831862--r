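# Hierarchical clustering of binary clinical traits and enrichment tests.
#
# Patients are clustered on their 0/1 trait vectors with Euclidean
# distance and complete linkage (on 0/1 data the Euclidean distance is
# sqrt(Hamming)).  Missing entries are imputed as 0 for the clustering
# step only ("not recorded" is read as "not observed positive"); the
# enrichment tests use non-missing entries only.

#' Cluster patients on binary clinical traits
#'
#' @param traits data frame with `patient_id` plus 0/1/NA trait columns
#'   (see [read_traits()]), or a numeric matrix with patient row names.
#' @param k number of clusters to cut (default 2).
#' @param qualitative optional named logical vector (missense carrier
#'   status by patient id); when supplied with `k = 2`, cluster labels are
#'   oriented so cluster 1 has the higher missense fraction.
#' @return object of class `trait_clusters`: `assignment` (named integer),
#'   `hclust` (the dendrogram), `matrix` (imputed 0/1 matrix),
#'   `missingness` (per-trait NA fraction of the input).
#' @export
cluster_traits <- function(traits, k = 2L, qualitative = NULL) {
  m <- as_trait_matrix(traits)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 patients and 2 traits", call. = FALSE)
  if (k < 1L || k > nrow(m)) stop("k must be in [1, n]", call. = FALSE)
  missingness <- colMeans(is.na(m))
  mi <- m
  mi[is.na(mi)] <- 0L
  hc <- stats::hclust(stats::dist(mi, method = "euclidean"),
                      method = "complete")
  assignment <- stats::cutree(hc, k = k)
  if (k == 2L && !is.null(qualitative)) {
    fr <- vapply(1:2, function(cl) {
      ids <- names(assignment)[assignment == cl]
      mean(qualitative[ids], na.rm = TRUE)
    }, numeric(1))
    if (fr[2] > fr[1]) assignment <- 3L - assignment
  }
  structure(list(assignment = assignment, hclust = hc, matrix = mi,
                 missingness = missingness),
            class = "trait_clusters")
}

as_trait_matrix <- function(traits) {
  if (is.matrix(traits)) {
    m <- traits
  } else {
    stopifnot(is.data.frame(traits), "patient_id" %in% names(traits))
    m <- as.matrix(traits[setdiff(names(traits), "patient_id")])
    rownames(m) <- traits$patient_id
  }
  storage.mode(m) <- "integer"
  if (any(!m %in% c(0L, 1L, NA)))
    stop("trait entries must be 0, 1 or NA", call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicate patient ids", call. = FALSE)
  m
}

#' Cut a dendrogram into k clusters
#'
#' @param hc an `hclust` object (or `trait_clusters`).
#' @param k number of clusters, 1 <= k <= n.
#' @return named integer cluster labels.
#' @export
cut_clusters <- function(hc, k = 2L) {
  if (inherits(hc, "trait_clusters")) hc <- hc$hclust
  n <- length(hc$order)
  if (k < 1L || k > n) stop("k must be in [1, n]", call. = FALSE)
  stats::cutree(hc, k = k)
}

#' @export
print.trait_clusters <- function(x, ...) {
  tab <- table(x$assignment)
  cat("Trait clustering (Euclidean distance, complete linkage)\n")
  cat(sprintf("  %d patients x %d traits; clusters: %s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
plot.trait_clusters <- function(x, ...) {
  graphics::plot(x$hclust, labels = FALSE, main = "Clinical trait clusters",
                 xlab = "", sub = "", ...)
  invisible(x)
}

#' Per-trait enrichment between two clusters
#'
#' For each trait, forms the 2x2 table (cluster x trait-positive) over
#' non-missing entries and applies the Yates-corrected chi-squared test.
#' Traits with a zero marginal are reported untestable (`p_value = NA`)
#' rather than failing.
#'
#' @param traits trait data frame or matrix (with NAs allowed).
#' @param clusters a `trait_clusters` object or named cluster vector.
#' @param alpha flag threshold (default 0.05).
#' @return data frame with one row per trait: positive fractions per
#'   cluster, `statistic`, `p_value`, `flag` (p < alpha) and `direction`
#'   (cluster with the higher positive fraction).
#' @export
trait_enrichment <- function(traits, clusters, alpha = 0.05) {
  m <- as_trait_matrix(if (inherits(traits, "trait_clusters"))
    traits$matrix else traits)
  assignment <- if (inherits(clusters, "trait_clusters"))
    clusters$assignment else clusters
  if (length(unique(assignment)) != 2L)
    stop("exactly 2 clusters required", call. = FALSE)
  ids <- intersect(rownames(m), names(assignment))
  m <- m[ids, , drop = FALSE]
  cl <- assignment[ids]
  rows <- lapply(colnames(m), function(tr) {
    v <- m[, tr]
    ok <- !is.na(v)
    a <- sum(v[ok & cl == 1L]); b <- sum(ok & cl == 1L) - a
    c_ <- sum(v[ok & cl == 2L]); d <- sum(ok & cl == 2L) - c_
    f1 <- if (a + b > 0) a / (a + b) else NA_real_
    f2 <- if (c_ + d > 0) c_ / (c_ + d) else NA_real_
    res <- tryCatch(chi2_2x2(a, b, c_, d),
                    error = function(e) list(statistic = NA_real_,
                                             p_value = NA_real_))
    data.frame(trait = tr, frac_cluster1 = f1, frac_cluster2 = f2,
               statistic = res$statistic, p_value = res$p_value,
               flag = !is.na(res$p_value) && res$p_value < alpha,
               direction = if (is.na(f1) || is.na(f2) || f1 == f2) "none"
                           else if (f1 > f2) "cluster1" else "cluster2",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Missense enrichment between two clusters
#'
#' Tests whether missense (qualitative) carriers are over-represented in
#' one cluster with the Yates-corrected chi-squared on the 2x2 table
#' (cluster x missense).
#'
#' @param clusters a `trait_clusters` object or named cluster vector.
#' @param qualitative named logical vector, TRUE for missense carriers;
#'   every clustered patient must be present.
#' @return list with the 2x2 `table`, `statistic`, `p_value` and the
#'   per-cluster missense percentages (1 d.p.).
#' @export
missense_enrichment <- function(clusters, qualitative) {
  assignment <- if (inherits(clusters, "trait_clusters"))
    clusters$assignment else clusters
  missing <- setdiff(names(assignment), names(qualitative))
  missing <- union(missing,
                   names(assignment)[is.na(qualitative[names(assignment)])])
  if (length(missing))
    stop("no qualitative/quantitative flag for patient(s): ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  q <- qualitative[names(assignment)]
  a <- sum(q & assignment == 1L); b <- sum(!q & assignment == 1L)
  c_ <- sum(q & assignment == 2L); d <- sum(!q & assignment == 2L)
  res <- chi2_2x2(a, b, c_, d)
  list(table = res$table, statistic = res$statistic,
       p_value = res$p_value,
       pct_cluster1 = ratio_pct(a, a + b),
       pct_cluster2 = ratio_pct(c_, c_ + d))
}
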