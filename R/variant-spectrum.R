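# HGVS cDNA variant parsing and consequence classification for the type I
# collagen genes.
#
# cDNA coordinates follow HGVS: position 1 is the A of the initiator ATG,
# intronic positions carry signed offsets (c.805-2 is two bases upstream
# of coding position 805).  Qualitative mutations are the missense
# (structure-altering) ones; all non-missense consequences (nonsense,
# frameshift, splicing, other) are quantitative, the haploinsufficiency
# route.  Glycine substitutions in the Gly-X-Y triple-helical repeat are
# flagged separately as the classic severe class.

normalize_hgvs <- function(s) {
  s <- gsub("[‒–—−]", "-", s)  # dashes -> hyphen-minus
  gsub("[[:space:]]", "", s)
}

#' Parse an HGVS cDNA variant string
#'
#' Supports substitutions, deletions, duplications, insertions and
#' deletion-insertions over single positions or ranges, with optional
#' intronic offsets.  En-dash and spacing variants of printed notation
#' (e.g. `"c.805–2A > G"`) are normalised before parsing.
#'
#' @param s a single HGVS string such as `"c.2461G>A"`, `"c.805-2A>G"` or
#'   `"c.2943delT"`.
#' @return list with `position`, `offset`, `position2`, `offset2` (NA for
#'   single-position variants), `ref`, `alt` (NA where not applicable) and
#'   `kind` in sub/del/dup/ins/delins.
#' @export
parse_hgvs_c <- function(s) {
  stopifnot(length(s) == 1L)
  raw <- s
  s <- normalize_hgvs(s)
  if (!grepl("^c\\.", s))
    stop("not an HGVS cDNA string: ", raw, call. = FALSE)
  body <- sub("^c\\.", "", s)
  pos_re <- "(\\d+)([+-]\\d+)?"
  parse_pos <- function(p, o) list(position = as.integer(p),
                                   offset = if (o == "") 0L else
                                     as.integer(o))
  # substitution: POS[OFF]R>A
  m <- regmatches(body, regexec(paste0("^", pos_re, "([ACGT])>([ACGT])$"),
                                body))[[1]]
  if (length(m)) {
    p <- parse_pos(m[2], m[3])
    return(list(position = p$position, offset = p$offset,
                position2 = NA_integer_, offset2 = NA_integer_,
                ref = m[4], alt = m[5], kind = "sub"))
  }
  # del/dup/ins/delins with optional range and trailing sequence
  m <- regmatches(body, regexec(
    paste0("^", pos_re, "(?:_", pos_re, ")?",
           "(delins|del|dup|ins)([ACGT]*)$"), body))[[1]]
  if (length(m)) {
    p1 <- parse_pos(m[2], m[3])
    has2 <- m[4] != ""
    p2 <- if (has2) parse_pos(m[4], m[5]) else
      list(position = NA_integer_, offset = NA_integer_)
    kind <- m[6]
    if (kind == "ins" && !has2)
      stop("insertion requires a position range: ", raw, call. = FALSE)
    return(list(position = p1$position, offset = p1$offset,
                position2 = p2$position, offset2 = p2$offset,
                ref = NA_character_,
                alt = if (m[7] == "") NA_character_ else m[7],
                kind = kind))
  }
  stop("unsupported HGVS syntax: ", raw, call. = FALSE)
}

parse_hgvs_p <- function(s) {
  if (is.na(s) || s == "") return(NULL)
  s <- normalize_hgvs(s)
  s <- gsub("[()]", "", sub("^p\\.", "", s))
  if (grepl("fs", s)) return(list(kind = "fs"))
  if (grepl("(Ter|\\*)$", s)) return(list(kind = "stop"))
  m <- regmatches(s, regexec("^([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})$",
                             s))[[1]]
  if (length(m))
    return(list(kind = "sub", ref = m[2], codon = as.integer(m[3]),
                alt = m[4]))
  list(kind = "other")
}

#' Load an exon model in cDNA coordinates
#'
#' Reads a BED-like TSV with columns `transcript`, `gene`, `exon`, `start`,
#' `end` (1-based inclusive cDNA coordinates) and validates that the exons
#' of each transcript are ordered, contiguous and non-overlapping.  The
#' packaged default is a synthetic exon model for NM_000088.4 (COL1A1, 51
#' exons) and NM_000089.4 (COL1A2, 52 exons): exon counts, coding lengths
#' and the splice-relevant boundaries match the real transcripts, interior
#' boundaries are synthetic.
#'
#' @param path TSV path; default = packaged synthetic model.
#' @return data frame of exons.
#' @export
load_exon_model <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "col1_exons_synthetic.tsv",
                        package = "oigrowth")
  ex <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript", "gene", "exon", "start", "end")
  if (!all(need %in% names(ex)))
    stop("exon model needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  for (tx in unique(ex$transcript)) {
    e <- ex[ex$transcript == tx, ]
    e <- e[order(e$exon), ]
    if (any(e$start > e$end) ||
        any(e$start[-1] != e$end[-nrow(e)] + 1L))
      stop("exons of ", tx, " not contiguous/ordered", call. = FALSE)
  }
  ex
}

exon_of <- function(gene, position, offset, exons) {
  e <- exons[exons$gene == gene, ]
  if (!nrow(e)) return(NA_integer_)
  if (!is.na(offset) && offset != 0L) {
    # intronic: map to the flanking exon boundary
    if (offset > 0L) {
      hit <- which(e$end == position)
      if (length(hit)) return(e$exon[hit[1L]])
    } else {
      hit <- which(e$start == position)
      if (length(hit)) return(e$exon[hit[1L]])
    }
  }
  hit <- which(e$start <= position & position <= e$end)
  if (length(hit)) e$exon[hit[1L]] else NA_integer_
}

classify_one <- function(gene, cdna, protein, exons) {
  cv <- parse_hgvs_c(cdna)
  pv <- parse_hgvs_p(protein)
  intronic <- cv$offset != 0L ||
    (!is.na(cv$offset2) && cv$offset2 != 0L)
  consequence <- NULL
  if (intronic) {
    consequence <- "splicing"
  } else if (cv$kind == "sub") {
    if (!is.null(pv) && pv$kind == "stop") consequence <- "nonsense"
    else if (!is.null(pv) && pv$kind == "fs")
      stop("cDNA substitution but protein frameshift: ", cdna, " vs ",
           protein, call. = FALSE)
    else if (!is.null(pv) && pv$kind == "sub") {
      codon <- (cv$position - 1L) %/% 3L + 1L
      if (pv$codon != codon)
        stop("codon mismatch between ", cdna, " (codon ", codon,
             ") and ", protein, call. = FALSE)
      consequence <- "missense"
    } else consequence <- "other"
  } else {
    # coding indel: frameshift when the net length change is not 3n
    span <- if (is.na(cv$position2)) 1L else
      cv$position2 - cv$position + 1L
    len <- switch(cv$kind,
      del = span,
      dup = span,
      ins = if (is.na(cv$alt)) 1L else nchar(cv$alt),
      delins = abs(span - if (is.na(cv$alt)) 0L else nchar(cv$alt)))
    consequence <- if (!is.null(pv) && pv$kind == "fs") "frameshift"
      else if (len %% 3L != 0L) "frameshift" else "other"
  }
  codon <- if (!intronic && cv$kind == "sub")
    (cv$position - 1L) %/% 3L + 1L else NA_integer_
  gly <- !is.null(pv) && pv$kind == "sub" && identical(pv$ref, "Gly")
  canonical <- intronic &&
    abs(cv$offset) %in% 1:2
  data.frame(gene = gene, cdna_hgvs = cdna,
             protein_hgvs = if (is.null(protein) || is.na(protein)) ""
                            else protein,
             consequence = consequence,
             qualitative = consequence == "missense",
             glycine_substitution = isTRUE(gly),
             canonical_splice = canonical,
             codon = codon,
             exon_index = exon_of(gene, cv$position, cv$offset, exons),
             stringsAsFactors = FALSE)
}

#' Classify variants by consequence
#'
#' Parses each variant's cDNA (and optional protein) HGVS string and
#' assigns a consequence class: `splicing` for intronic offsets (canonical
#' if within +/-2 of the exon boundary), `nonsense` for stop gains,
#' `frameshift` for length changes not divisible by 3 (or protein `fs`),
#' `missense` for coding substitutions with a single-residue protein
#' change, `other` otherwise.  Qualitative = missense; everything else is
#' quantitative.  Contradictory cDNA/protein annotations (wrong codon,
#' substitution vs frameshift) raise an error naming both.
#'
#' @param variants data frame with columns `gene`, `cdna_hgvs` and
#'   optionally `protein_hgvs` (and `patient_id`, carried through).
#' @param exons exon model from [load_exon_model()].
#' @return data frame with one row per input variant: consequence class,
#'   `qualitative`, `glycine_substitution`, `canonical_splice`, `codon`
#'   and `exon_index` (intronic variants map to the flanking exon).
#' @export
classify_variants <- function(variants, exons = load_exon_model()) {
  if (is.null(variants$protein_hgvs)) variants$protein_hgvs <- NA_character_
  out <- do.call(rbind, lapply(seq_len(nrow(variants)), function(i)
    classify_one(variants$gene[i], variants$cdna_hgvs[i],
                 variants$protein_hgvs[i], exons)))
  if (!is.null(variants$patient_id))
    out <- cbind(patient_id = variants$patient_id, out)
  rownames(out) <- NULL
  out
}

consequence_levels <- c("missense", "nonsense", "frameshift", "splicing",
                        "other")

#' Summarise the mutational spectrum
#'
#' Per-gene consequence counts and percentages (1 d.p.), a recurrence
#' table collapsing identical (gene, cDNA) events, and a per-exon tally
#' for locus diagrams.
#'
#' @param records classified variants from [classify_variants()].
#' @return object of class `variant_spectrum`: `counts` (gene x class
#'   matrix), `percentages`, `recurrence` and `by_exon` data frames.
#' @export
spectrum_summary <- function(records) {
  if (!nrow(records))
    return(structure(list(counts = NULL, percentages = NULL,
                          recurrence = NULL, by_exon = NULL),
                     class = "variant_spectrum"))
  counts <- table(factor(records$gene),
                  factor(records$consequence,
                         levels = consequence_levels))
  counts <- unclass(counts)
  pct <- round(100 * counts / rowSums(counts), 1)
  rec <- stats::aggregate(
    list(n = records$gene),
    by = list(gene = records$gene, cdna_hgvs = records$cdna_hgvs,
              consequence = records$consequence),
    FUN = length)
  rec <- rec[order(-rec$n, rec$gene, rec$cdna_hgvs), ]
  rownames(rec) <- NULL
  by_exon <- stats::aggregate(
    list(n = records$gene),
    by = list(gene = records$gene, exon = records$exon_index,
              consequence = records$consequence),
    FUN = length)
  structure(list(counts = counts, percentages = pct, recurrence = rec,
                 by_exon = by_exon),
            class = "variant_spectrum")
}

#' @export
print.variant_spectrum <- function(x, ...) {
  cat("Variant spectrum\n")
  if (is.null(x$counts)) { cat("  (empty)\n"); return(invisible(x)) }
  for (g in rownames(x$counts)) {
    cat(" ", g, ": ", sum(x$counts[g, ]), " events; ",
        paste(sprintf("%s %.1f%%", colnames(x$counts),
                      x$percentages[g, ]), collapse = ", "), "\n",
        sep = "")
  }
  top <- utils::head(x$recurrence[x$recurrence$n > 1, ], 5)
  if (nrow(top)) {
    cat("  recurrent:",
        paste(sprintf("%s %s (n=%d)", top$gene, top$cdna_hgvs, top$n),
              collapse = "; "), "\n")
  }
  invisible(x)
}

#' Chi-squared test of variant-type composition between genes
#'
#' Compares per-gene consequence-class counts with the uncorrected
#' Pearson chi-squared ([chi2_rxc()]); classes with a zero column marginal
#' are dropped with a warning (zero cells within a represented class are
#' kept).
#'
#' @param counts gene x consequence count matrix (e.g.
#'   `spectrum_summary(x)$counts`).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
composition_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L)
    stop("need counts for at least 2 genes", call. = FALSE)
  zero <- colSums(counts) == 0
  if (any(zero)) {
    warning("dropping empty class(es): ",
            paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
    counts <- counts[, !zero, drop = FALSE]
  }
  if (ncol(counts) < 2L)
    stop("need at least 2 consequence classes", call. = FALSE)
  chi2_rxc(counts)
}
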