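# oigrowth

Growth-curve reference modelling and treatment-response analysis for
osteogenesis imperfecta (OI) cohorts.

OI cohort studies face two linked questions: whether bisphosphonate (BP)
treatment improves bone mineral density (BMD) accrual — and at which ages —
and how the *COL1A1*/*COL1A2* variant spectrum maps onto clinical severity.
`oigrowth` is aimed at biostatisticians and clinical researchers working
with longitudinal DXA/growth records and curated variant tables. It
provides the full analysis chain:

* **Stratified control selection** — keep all non-OI records below an age
  cutoff; cap each (5-year bin × sex × metric) cell above it at a quota
  derived from the control:case ratio of the last well-populated juvenile
  bin.
* **Normal-growth reference curves** — LOESS (span 0.75, degree 2, tricube
  weights) per metric and sex, evaluated by re-solving the local fit at any
  age in the training domain.
* **The response angle.** For successive readings `(t1, b1) → (t2, b2)` of
  one patient, with actual slope `k' = (b2 − b1)/(t2 − t1)` and expected
  slope `k = [f(t2) − f(t1)]/(t2 − t1)` on the reference curve `f`,

  α = arctan(k′/C′) − arctan(k/C),

  where `C = C'` is the reference curve's mean slope, making α
  dimensionless and unit-invariant: α > 0 means growing faster than
  unaffected peers, α < 0 slower.
* **Stratified Wilcoxon signed-rank tests** of α = 0 per
  (metric × sex × BP history × age group), with `*`/`**` marks at
  p < 0.05 / p < 0.01.
* **Clinical-trait clustering** (Euclidean distance, complete linkage, 0/1
  traits) with per-trait and missense-carrier enrichment via
  Yates-corrected chi-squared tests.
* **HGVS variant classification** for the type I collagen genes: parse
  cDNA strings, classify missense / nonsense / frameshift / splicing /
  other, flag glycine substitutions, map to exons.
* **A synthetic cohort generator** with known ground truth, so every stage
  of the pipeline is testable end to end.

## Worked example

```r
library(oigrowth)

co  <- simulate_cohort(sim_config(n_oi = 120, n_nonoi = 250, seed = 42))
fit <- bp_response(co$measurements)
print(fit)
```

```
Bisphosphonate treatment-response analysis
  1330 control records, 4 reference curves, 614 pairs
  48 strata tested, 11 marked significant
   ** spine_bmd/female 10-15 BP=TRUE   median alpha +0.140 (n=24, p=1.19e-07)
   ** spine_bmd/male 10-15 BP=TRUE     median alpha +0.103 (n=44, p=4.76e-07)
   ** height/female 10-15 BP=TRUE      median alpha -0.121 (n=24, p=0.000963)
   ** height/male 15-20 BP=TRUE        median alpha -0.117 (n=24, p=0.00792)
   ...
```

The generator injected a BP boost to BMD accrual only inside ages 10–15:
the fitted analysis marks exactly the treated spine-BMD 10–15 strata as
significantly *positive* (bone density responding to treatment), while
height strata are flat or significantly *negative* — height does not
respond. `summary(fit)` returns the full stratum table;
`plot(fit, "spine_bmd")` draws the angle distributions.

The genotype–phenotype side:

```r
truth <- co$truth[match(co$traits$patient_id, co$truth$patient_id), ]
flags <- setNames(truth$missense, truth$patient_id)
cl    <- cluster_traits(co$traits, k = 2, qualitative = flags)
missense_enrichment(cl, flags)
```

```
Trait clustering (Euclidean distance, complete linkage)
  82 patients x 20 traits; clusters: 1 (n=48), 2 (n=34)
missense: cluster 1 91.7% vs cluster 2 26.5% (chi2 p = 4.94e-09)
```

Patients split into a severe and a milder trait cluster, and missense
(qualitative) carriers are strongly enriched in the severe one. On the
published 90-patient table (33/39 missense in cluster 1 vs 29/51 in
cluster 2) the same test gives `chi2_2x2(33, 6, 29, 22)` → p = 0.0096.

Variant spectra:

```r
spectrum_summary(classify_variants(co$variants))
```

```
Variant spectrum
 COL1A1: 43 events; missense 65.1%, nonsense 4.7%, frameshift 14.0%, splicing 16.3%, other 0.0%
 COL1A2: 39 events; missense 64.1%, nonsense 0.0%, frameshift 12.8%, splicing 15.4%, other 7.7%
  recurrent: COL1A1 c.590G>A (n=10); COL1A1 c.2461G>A (n=9); ...
```

## Package layout

* `R/` — implementation: synthetic cohort, table IO, control selection,
  reference curves, response angles, stratified tests, trait clustering,
  variant classification, and the `bp_response()` driver.
* `inst/extdata/` — packaged variant panel and the synthetic exon model
  (51/52 exons in cDNA coordinates; see the vignette for its caveats).
* `vignettes/oi-growth-response.Rmd` — the methods vignette: model,
  assumptions, parameter choices, calibration, limitations.
* `tests/testthat/` — unit, property and end-to-end tests with
  independent oracles.
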