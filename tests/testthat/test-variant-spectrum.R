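test_that("HGVS cDNA strings parse into structured fields", {
  v <- parse_hgvs_c("c.2461G>A")
  expect_equal(v[c("position", "offset", "ref", "alt", "kind")],
               list(position = 2461L, offset = 0L, ref = "G", alt = "A",
                    kind = "sub"))
  v <- parse_hgvs_c("c.805-2A>G")
  expect_equal(v$position, 805L)
  expect_equal(v$offset, -2L)
  v <- parse_hgvs_c("c.792+2T>G")
  expect_equal(v$offset, 2L)
  v <- parse_hgvs_c("c.2943delT")
  expect_equal(v$kind, "del")
  expect_equal(v$position, 2943L)
  v <- parse_hgvs_c("c.1984_1986del")
  expect_equal(v$position2, 1986L)
  v <- parse_hgvs_c("c.100_101insT")
  expect_equal(v$kind, "ins")

  # printed-notation variants: en-dash and spaces normalise away
  v <- parse_hgvs_c("c.805–2A > G")
  expect_equal(v$offset, -2L)

  expect_error(parse_hgvs_c("c.12X>Y"), "unsupported")
  expect_error(parse_hgvs_c("g.123A>G"), "cDNA")
  expect_error(parse_hgvs_c("c.100insT"), "range")
})

test_that("the printed variants classify to their published classes", {
  vars <- data.frame(
    gene = c("COL1A1", "COL1A2", "COL1A1", "COL1A2", "COL1A1"),
    cdna_hgvs = c("c.2461G>A", "c.792+2T>G", "c.805-2A>G", "c.2943delT",
                  "c.2299G>A"),
    protein_hgvs = c("p.Gly821Ser", NA, NA, NA, "p.Gly767Ser"),
    stringsAsFactors = FALSE)
  cls <- classify_variants(vars)
  expect_equal(cls$consequence,
               c("missense", "splicing", "splicing", "frameshift",
                 "missense"))
  expect_equal(cls$qualitative, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_true(cls$glycine_substitution[1])
  expect_true(all(cls$canonical_splice[2:3]))
  expect_equal(cls$codon, c(821L, NA, NA, NA, 767L))
})

test_that("codon arithmetic and annotation contradictions are enforced", {
  expect_equal(classify_variants(data.frame(
    gene = "COL1A1", cdna_hgvs = "c.3803A>T",
    protein_hgvs = "p.Asp1268Val"))$codon, 1268L)
  # protein codon disagreeing with the cDNA position
  expect_error(classify_variants(data.frame(
    gene = "COL1A1", cdna_hgvs = "c.2461G>A",
    protein_hgvs = "p.Gly820Ser")), "codon mismatch")
  # substitution with a frameshift protein annotation
  expect_error(classify_variants(data.frame(
    gene = "COL1A1", cdna_hgvs = "c.2461G>A",
    protein_hgvs = "p.Gly821fs")), "frameshift")
  # nonsense and in-frame calls
  cls <- classify_variants(data.frame(
    gene = c("COL1A1", "COL1A2", "COL1A1"),
    cdna_hgvs = c("c.3076C>T", "c.1984_1986del", "c.2005dupC"),
    protein_hgvs = c("p.Arg1026Ter", NA, NA)))
  expect_equal(cls$consequence, c("nonsense", "other", "frameshift"))
  expect_false(any(cls$qualitative))
})

test_that("the exon model validates and places variants", {
  ex <- load_exon_model()
  expect_equal(sum(ex$gene == "COL1A1"), 51)
  expect_equal(sum(ex$gene == "COL1A2"), 52)
  # splice variants land on the flanking exon boundary
  cls <- classify_variants(data.frame(
    gene = c("COL1A1", "COL1A2"),
    cdna_hgvs = c("c.805-2A>G", "c.792+2T>G"),
    protein_hgvs = NA), exons = ex)
  a1 <- ex[ex$gene == "COL1A1", ]
  expect_equal(cls$exon_index[1], a1$exon[a1$start == 805])
  a2 <- ex[ex$gene == "COL1A2", ]
  expect_equal(cls$exon_index[2], a2$exon[a2$end == 792])
  # coding position inside an exon
  cls <- classify_variants(data.frame(
    gene = "COL1A1", cdna_hgvs = "c.2461G>A",
    protein_hgvs = "p.Gly821Ser"), exons = ex)
  hit <- a1[a1$start <= 2461 & 2461 <= a1$end, ]
  expect_equal(cls$exon_index, hit$exon)

  # corrupt model (gap between exons) is refused
  bad <- ex
  bad$start[bad$gene == "COL1A1" & bad$exon == 2] <-
    bad$start[bad$gene == "COL1A1" & bad$exon == 2] + 1
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(bad, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_exon_model(path), "contiguous")
})

test_that("every packaged panel variant parses and classifies as labelled", {
  panel <- utils::read.delim(system.file("extdata",
                                         "col1_variant_panel.tsv",
                                         package = "oigrowth"),
                             stringsAsFactors = FALSE)
  cls <- classify_variants(panel)
  expect_equal(cls$consequence, panel$class)
  expect_identical(cls$qualitative, panel$class == "missense")
  expect_true(all(cls$glycine_substitution[grepl("p.Gly",
                                                 panel$protein_hgvs)]))
})

test_that("spectrum summaries count, percentage and collapse recurrences", {
  set.seed(67)
  recs <- data.frame(
    gene = rep("COL1A1", 63),
    cdna_hgvs = c(rep("c.2461G>A", 8), sprintf("c.%dG>A", 3 * (1:55) + 1)),
    protein_hgvs = NA, stringsAsFactors = FALSE)
  recs$consequence <- rep(c("missense", "splicing", "frameshift",
                            "nonsense"), c(36, 11, 10, 6))
  recs$exon_index <- 1L
  sm <- spectrum_summary(recs)
  expect_equal(unname(sm$counts["COL1A1", "missense"]), 36)
  expect_equal(unname(sm$percentages["COL1A1", "missense"]), 57.1)
  expect_equal(sum(sm$percentages["COL1A1", ]), 100, tolerance = 0.1)
  expect_equal(sm$recurrence$n[1], 8)
  expect_equal(sm$recurrence$cdna_hgvs[1], "c.2461G>A")
  expect_null(spectrum_summary(recs[0, ])$counts)
})

test_that("composition tests drop empty classes and match the oracle", {
  counts <- rbind(COL1A1 = c(missense = 30, splicing = 10, nonsense = 5),
                  COL1A2 = c(missense = 45, splicing = 9, nonsense = 0))
  r <- composition_test(counts)
  expect_equal(r$statistic, chi2_rxc_oracle(counts)$statistic,
               tolerance = 1e-9)

  # proportional compositions carry no signal
  prop <- rbind(c(20, 10, 5), c(40, 20, 10))
  expect_equal(composition_test(prop)$p_value, 1, tolerance = 1e-9)

  # a class absent from every gene is dropped with a warning
  with_zero <- cbind(counts, other = c(0, 0))
  expect_warning(r2 <- composition_test(with_zero), "other")
  expect_equal(r2$statistic, r$statistic)

  set.seed(71)
  for (i in 1:50) {
    tab <- matrix(rpois(8, 10) + 1, 2, 4)
    expect_equal(composition_test(tab)$statistic,
                 chi2_rxc_oracle(tab)$statistic, tolerance = 1e-9)
  }
})
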