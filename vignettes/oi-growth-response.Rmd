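---
title: "Growth reference curves and the treatment-response angle in osteogenesis imperfecta cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth reference curves and the treatment-response angle in osteogenesis imperfecta cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oigrowth)
```

## The problem

Osteogenesis imperfecta (OI) is a heritable connective-tissue disorder,
most often caused by variants in the type I collagen genes *COL1A1* and
*COL1A2*, in which bone fragility and growth deficits dominate the
clinical picture. Two questions recur in cohort studies of OI:

1. **Does anti-resorptive (bisphosphonate, BP) treatment improve bone
   mineral density (BMD) accrual, and if so at which ages?** Longitudinal
   DXA scans of patients must be compared against the normal growth of
   unaffected controls, with few scans per patient and an age-skewed
   control archive.
2. **How do the genetics map onto the clinic?** Missense ("qualitative")
   collagen variants disrupt the triple helix and tend to produce more
   severe phenotypes than haploinsufficiency-type ("quantitative")
   variants — nonsense, frameshift and splice-site changes.

`oigrowth` implements the full analysis chain for both questions, plus a
synthetic cohort generator that reproduces the statistical structure the
chain assumes, so every stage can be validated against known ground
truth without access to patient data.

## Stratified control selection

Hospital archives hold few paediatric control scans and tens of
thousands of adult ones, the mirror image of an OI referral cohort. The
selection procedure (`select_controls()`) therefore:

* keeps **all** control records below an age cutoff (default 20 years);
* above the cutoff, samples each (5-year age bin × sex × metric) cell
  down to a fixed quota, without replacement, reproducibly from a seed.

Quotas default to 26 spine-BMD and 12 hip-BMD records per cell (height
and weight ride along with spine scans). `derive_quota()` recomputes
them from data as `round(ratio × cases)`, where the ratio of controls to
cases is taken from the last well-populated juvenile bin (15–20 years,
roughly 1:4 in the motivating cohort). Age bins are half-open `[lo, hi)`
so that every age maps to exactly one bin; the printed bin labels of
cohort studies ("15–20", "20–25") are ambiguous at the boundary and the
half-open convention resolves this deterministically.

## The normal-growth reference curve

Controls for one metric and sex are smoothed with LOESS — locally
weighted polynomial regression with tricube weights — via
`fit_reference()`, using the conventional defaults: span 0.75, local
degree 2, Gaussian (non-robust) family. Two numerical choices matter:

* **Direct evaluation.** The local polynomial is re-solved at every
  query age (`surface = "direct"`), rather than interpolating a
  precomputed grid. The expected slope between two arbitrary ages,
  `k = [f(t2) − f(t1)]/(t2 − t1)`, is then well defined everywhere in
  the training domain.
* **No extrapolation.** Evaluation outside the training age range is an
  error; pairs that stray outside the domain are dropped with a warning
  rather than silently extrapolated.

With span 1, a degree-2 fit reproduces any quadratic exactly (a local
regression identity the test suite checks against an independent
textbook implementation).

## The response angle

For two successive readings `(t1, b1) → (t2, b2)` of one patient and
metric, the actual slope is `k' = (b2 − b1)/(t2 − t1)` and the expected
slope `k` comes from the reference curve. The response statistic is the
angle

$$\alpha = \arctan(k'/C') - \arctan(k/C),$$

positive when the patient grows faster than unaffected peers, negative
when slower, zero on-reference. `C` and `C'` are normalising scales that
make angles comparable between metrics measured in different units.
Their exact values are a genuinely open design point: we define both as
the reference curve's **mean slope over its domain**,
`C = (f(hi) − f(lo))/(hi − lo)` (`ref_scale()`), with `C' = C` per
metric and sex. This makes `α` dimensionless and exactly invariant to a
change of units (rescaling a metric rescales `k`, `k'` and `C`
identically), which is the operational meaning of cross-metric
comparability. Because any such scaling convention is one of many,
numeric agreement with other implementations of the same idea can be
claimed only up to the choice of `C`; the qualitative structure (signs,
ordering, significance patterns) does not depend on it.

Pairs are dated at their age midpoint `(t1 + t2)/2` and assigned that
midpoint's 5-year bin — symmetric, and the natural dating of a growth
rate measured over an interval. A pair counts as BP-exposed when the
patient reported prior bisphosphonate treatment at or before its second
reading.

## Stratified testing

`test_strata()` runs a Wilcoxon signed-rank test of `α = 0` per stratum
(metric × sex × BP history × age group): zeros dropped, exact null
distribution for n ≤ 25 without ties, normal approximation with
continuity correction otherwise. Tests are two-sided with the direction
reported from the median's sign — treatment response can show up as
significantly *positive* (BMD under BP) or significantly *negative*
(height), and a one-sided test would hide the latter. Marks follow the
usual convention (`*` p < 0.05, `**` p < 0.01); strata smaller than 5
pairs are reported but never marked. No multiple-testing correction is
applied across strata or traits — the per-stratum p-values are
descriptive, mirroring how such panels are usually presented, and the
package's calibration tests quantify the per-test size instead.

## Trait clustering and enrichment

Binary clinical traits (about 20 per patient, missing entries allowed)
are clustered with Euclidean distance and complete linkage
(`cluster_traits()`); on 0/1 data the Euclidean distance is the square
root of the Hamming distance, so no scaling is applied. Missing entries
are imputed as 0 **for clustering only** — a trait not recorded is
treated as not observed positive — while the per-trait enrichment tests
(`trait_enrichment()`) use non-missing entries only; per-trait
missingness is reported alongside. With two clusters and carrier flags
supplied, labels are oriented so cluster 1 carries the higher missense
fraction. Tied merge heights are resolved by the agglomeration order of
`stats::hclust`, which is deterministic for a fixed row order; the
package's order-invariance guarantees therefore hold exactly on
tie-free distance matrices, and up to tie-breaking otherwise.

Enrichment of missense carriers between clusters
(`missense_enrichment()`) and per-trait cluster association use the
Yates-corrected chi-squared on 2×2 tables. The continuity correction is
deliberately on by default: it is the convention of the standard R
test, and the one under which published cluster-enrichment p-values of
this kind reproduce. Variant-type composition between genes uses the
uncorrected Pearson chi-squared on the r×c count table
(`composition_test()`), with empty classes dropped.

## Variant classification

`parse_hgvs_c()` parses the HGVS cDNA grammar needed for curated
collagen variant tables: substitutions, deletions, duplications,
insertions and delins, single positions or ranges, intronic offsets,
with printed-notation quirks (en-dashes, spaces) normalised away.
`classify_variants()` then assigns consequences:

* **splicing** — any intronic offset (canonical when within ±2 of the
  exon boundary);
* **nonsense** — stop-gain protein annotation;
* **frameshift** — indel length not divisible by 3, or a protein
  annotation ending in `fs`;
* **missense** — coding substitution with a single-residue protein
  change; the codon is checked against the cDNA position via
  `codon = (pos − 1) %/% 3 + 1`, and a mismatch is an error rather than
  a silent preference for one annotation;
* **other** — in-frame indels and anything unclassifiable.

Qualitative = missense; everything else is quantitative. Glycine
substitutions — the classic severe class in the Gly-X-Y triple-helical
repeat — are flagged separately.

Exon assignment uses a packaged exon model in cDNA coordinates
(`load_exon_model()`). The shipped model is **synthetic**: it has the
real exon counts (51 for *COL1A1*/NM_000088.4, 52 for
*COL1A2*/NM_000089.4), the real coding lengths, and exon boundaries at
the splice-relevant positions used by the packaged variant panel, but
interior boundaries are generated, not downloaded from NCBI. Users with
access to the real annotation can supply their own TSV in the same
format.

## What the synthetic cohort emulates

`simulate_cohort()` generates measurement, trait, variant and
ground-truth tables with the structure the analysis assumes. Defaults
were chosen once, to mirror a paediatric-dominated OI referral cohort,
and are documented here with their reasons:

* **Age structure.** Scan ages for OI patients follow a Beta(1.15, 2.6)
  shape over 1–38 years, giving median ≈ 11 and IQR ≈ 6–18 — the
  admission-age profile of a typical referral cohort. Control ages are
  uniform over the same range, mimicking an archive that spans all ages.
  A uniform OI age distribution was rejected: it parks a third of the
  response pairs at the right edge of the reference curve's domain,
  where any local-polynomial fit of a saturating trajectory turns down
  and biases adult-stratum angles positive. The Beta shape removes the
  artefact for the realistic reason — OI scan mass is paediatric.
* **Trajectories.** Height is a double logistic (childhood component
  plus pubertal spurt); BMD is a single logistic to an adult plateau,
  with spine and hip sharing shape but not plateau, so the two sites are
  strongly correlated by construction. Weight is derived from height
  through an age-varying BMI factor. All templates are monotone over the
  growth years.
* **OI deficit.** A multiplicative factor (default 0.8) on the noise-free
  trajectory level of OI patients.
* **BP effect.** For treated OI patients, the BMD accrual *rate* is
  multiplied by (1 + `bp_slope_boost`), default 2×, strictly inside the
  effect window (default ages 10–15); the trajectory stays continuous,
  so the boost moves slopes, not levels — matching a claim that is about
  growth-rate angles, not absolute BMD.
* **Measurement noise.** Gaussian, 1.5 cm/kg for height and weight,
  0.04 g/cm² for BMD.
* **Genetics and traits.** About 64% of OI patients carry a COL1
  variant; 62% of carriers are missense, drawn from a packaged panel of
  real and synthetic HGVS strings. Each carrier belongs to one of two
  latent trait clusters (severe cluster 1 with probability 0.8 for
  missense carriers, 0.2 otherwise); trait vectors are cluster templates
  with 10% flip noise and 5% missingness.

What the generator does **not** emulate: real DXA error structure
(heteroscedastic, device-dependent), informative visit timing (sicker
patients are scanned more often), treatment assignment confounded with
severity, family structure, and secular trends. Passing the recovery
tests therefore shows the pipeline detects the injected age-specific
effect under clean conditions — it does not certify causal
interpretability on observational clinical data, where BP-by-indication
confounding remains.

## Problem sizes and calibration

The validation suite runs the full pipeline on 50 replicate cohorts of
200 OI + 200 control patients and requires the injected 10–15-year BMD
effect to be flagged significantly positive in at least 90% of
replicates while treated height strata are flagged positive in at most
10%. Null calibration uses 2000 strata of 25 symmetric-null angles for
the signed-rank test, and 2000 balanced-trait tests on clusters of 250
patients for the Yates-corrected enrichment test; both hold the 5%
level within one percentage point. The balanced, moderately large null
configurations matter: the continuity correction is conservative for
small or skewed tables, which is the accepted price of its behaviour on
small counts.

## Known limitations

* The angle statistic treats pairs from the same patient as independent
  in the stratum tests; with 1–6 scans per patient the induced
  correlation is mild, but a clustered or mixed-model variant would be
  more defensible with denser data (and nonlinear mixed-effect growth
  models are exactly what the sparse-scan setting rules out).
* The normalising scale `C` is a convention; see above.
* The shipped exon model is synthetic in its interior boundaries.
* Euclidean/complete-linkage clustering of binary traits is sensitive
  to trait selection and to the 0-imputation of missing entries when
  missingness is informative.
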