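# Synthetic OI cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# mixed OI / non-OI cohort with 5-year age structure and both sexes,
# saturating height and BMD trajectories with a multiplicative OI deficit,
# an age-window-specific bisphosphonate (BP) boost to BMD accrual in
# treated OI patients, 1-6 scans per person, a two-latent-cluster binary
# trait matrix whose membership correlates with missense-carrier status,
# and HGVS-coded COL1A1/COL1A2 variant assignments.

#' Double-logistic height template
#'
#' Height in cm as a childhood logistic plus a pubertal-spurt logistic on
#' top of an infancy baseline: monotone, saturating, with one growth spurt.
#'
#' @param age ages in years.
#' @param p named list/vector with `h0` (infancy baseline, cm), `a1`, `r1`,
#'   `m1` (childhood amplitude, rate /yr, midpoint yr), `a2`, `r2`, `m2`
#'   (pubertal component).
#' @return heights in cm.
#' @export
height_template <- function(age, p) {
  p$h0 + p$a1 / (1 + exp(-p$r1 * (age - p$m1))) +
    p$a2 / (1 + exp(-p$r2 * (age - p$m2)))
}

#' Single-logistic BMD accrual template
#'
#' BMD in g/cm^2 rising from an infant baseline `b0` to an adult plateau
#' `plateau` with rate `r` and midpoint `m`.  Spine and hip share this
#' shape with different plateaus, so the two sites are strongly correlated
#' by construction.
#'
#' @param age ages in years.
#' @param p named list/vector with `b0`, `plateau`, `r`, `m`.
#' @return BMD in g/cm^2.
#' @export
bmd_template <- function(age, p) {
  p$b0 + (p$plateau - p$b0) / (1 + exp(-p$r * (age - p$m)))
}

default_height_params <- function() list(
  female = list(h0 = 50, a1 = 100, r1 = 0.45, m1 = 3.6, a2 = 16, r2 = 1.0, m2 = 11.5),
  male   = list(h0 = 50, a1 = 105, r1 = 0.45, m1 = 3.8, a2 = 22, r2 = 0.9, m2 = 13.5))

default_bmd_params <- function() list(
  female = list(spine_bmd = list(b0 = 0.30, plateau = 1.00, r = 0.55, m = 11.5),
                hip_bmd   = list(b0 = 0.28, plateau = 0.92, r = 0.55, m = 11.5)),
  male   = list(spine_bmd = list(b0 = 0.30, plateau = 1.05, r = 0.45, m = 12.5),
                hip_bmd   = list(b0 = 0.28, plateau = 1.00, r = 0.45, m = 12.5)))

#' Simulation configuration
#'
#' Parameters of the synthetic cohort.  Defaults emulate the structure of a
#' paediatric-dominated OI referral cohort: roughly 60% male, admission
#' ages 1-38, about 64% of OI patients carrying a type I collagen variant,
#' three quarters of OI patients BP-treated, and a BP boost to BMD accrual
#' confined to ages 10-15.
#'
#' @param n_oi,n_nonoi patient counts.
#' @param sex_ratio fraction male in \[0,1\].
#' @param visit_count_range integer (min, max) scans per person, min >= 1.
#' @param age_range (min, max) scan ages in years, within \[0,40\].
#' @param age_shape Beta(shape1, shape2) parameters shaping OI scan ages
#'   within `age_range`; the default (1.15, 2.6) reproduces a
#'   paediatric-dominated referral cohort (median about 11 years, IQR
#'   about 6-18 on the default 1-38 year range).  Control (non-OI) scan ages are
#'   uniform, mimicking an archive that spans all ages.
#' @param height_curve_params per-sex double-logistic parameters, see
#'   [height_template()].
#' @param bmd_curve_params per-sex, per-site logistic parameters, see
#'   [bmd_template()].
#' @param oi_deficit multiplicative factor in (0,1\] applied to OI
#'   noise-free trajectories.
#' @param bp_effect_window (lo, hi) ages in years within which BP boosts
#'   BMD accrual (default 10-15).
#' @param bp_slope_boost fractional increase of the BMD accrual rate inside
#'   the window for BP-treated OI patients (0 = no effect).
#' @param noise_sd named per-metric Gaussian measurement noise SD.
#' @param col1_fraction fraction of OI patients in the OI-COL1 group.
#' @param bp_treated_frac fraction of OI patients with prior BP treatment.
#' @param missense_fraction fraction of OI-COL1 patients carrying missense
#'   (qualitative) variants.
#' @param cluster1_prob probability of latent severe cluster 1 given
#'   missense / non-missense carrier status, length-2 numeric.
#' @param trait_flip_prob Bernoulli noise on cluster-template traits, in
#'   \[0, 0.5).
#' @param trait_missing_prob probability a trait entry is unrecorded.
#' @param min_two_frac fraction of patients guaranteed >= 2 scans so that
#'   successive-reading pairs exist.
#' @param seed integer RNG seed; identical configs give byte-identical
#'   output tables.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_oi = 187, n_nonoi = 400, sex_ratio = 0.6,
                       visit_count_range = c(1L, 6L), age_range = c(1, 38),
                       age_shape = c(1.15, 2.6),
                       height_curve_params = default_height_params(),
                       bmd_curve_params = default_bmd_params(),
                       oi_deficit = 0.8, bp_effect_window = c(10, 15),
                       bp_slope_boost = 1.0,
                       noise_sd = c(height = 1.5, weight = 1.5,
                                    spine_bmd = 0.04, hip_bmd = 0.04),
                       col1_fraction = 0.64, bp_treated_frac = 0.75,
                       missense_fraction = 0.62,
                       cluster1_prob = c(missense = 0.8, other = 0.2),
                       trait_flip_prob = 0.1, trait_missing_prob = 0.05,
                       min_two_frac = 0.8, seed = 1L) {
  cfg <- list(n_oi = n_oi, n_nonoi = n_nonoi, sex_ratio = sex_ratio,
              visit_count_range = as.integer(visit_count_range),
              age_range = age_range, age_shape = age_shape,
              height_curve_params = height_curve_params,
              bmd_curve_params = bmd_curve_params,
              oi_deficit = oi_deficit, bp_effect_window = bp_effect_window,
              bp_slope_boost = bp_slope_boost, noise_sd = noise_sd,
              col1_fraction = col1_fraction,
              bp_treated_frac = bp_treated_frac,
              missense_fraction = missense_fraction,
              cluster1_prob = cluster1_prob,
              trait_flip_prob = trait_flip_prob,
              trait_missing_prob = trait_missing_prob,
              min_two_frac = min_two_frac, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field) if (!ok)
    stop("invalid sim_config field: ", field, call. = FALSE)
  chk(cfg$n_oi >= 0 && cfg$n_nonoi >= 0, "n_oi/n_nonoi")
  for (f in c("sex_ratio", "col1_fraction", "bp_treated_frac",
              "missense_fraction", "min_two_frac", "trait_missing_prob"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f)
  chk(cfg$trait_flip_prob >= 0 && cfg$trait_flip_prob < 0.5, "trait_flip_prob")
  chk(cfg$visit_count_range[1] >= 1 &&
        cfg$visit_count_range[2] >= cfg$visit_count_range[1],
      "visit_count_range")
  chk(cfg$age_range[1] >= 0 && cfg$age_range[2] <= 40 &&
        cfg$age_range[2] > cfg$age_range[1], "age_range")
  chk(length(cfg$age_shape) == 2 && all(cfg$age_shape > 0), "age_shape")
  chk(all(cfg$noise_sd >= 0) &&
        all(metric_levels %in% names(cfg$noise_sd)), "noise_sd")
  chk(cfg$oi_deficit > 0 && cfg$oi_deficit <= 1, "oi_deficit")
  chk(cfg$bp_effect_window[2] > cfg$bp_effect_window[1], "bp_effect_window")
  chk(cfg$bp_slope_boost >= 0, "bp_slope_boost")
  chk(all(cfg$cluster1_prob >= 0 & cfg$cluster1_prob <= 1), "cluster1_prob")
  invisible(cfg)
}

# Noise-free trajectory value for one patient at given ages.
# OI patients sit at `deficit` times the non-OI template; BP-treated OI
# patients accrue BMD at (1 + boost) times their deficit-scaled rate while
# inside the effect window, so the boost acts on the slope, not the level.
trajectory_value <- function(metric, age, sex, oi, bp, cfg) {
  base <- switch(metric,
    height = height_template(age, cfg$height_curve_params[[sex]]),
    weight = {
      h <- height_template(age, cfg$height_curve_params[[sex]])
      bmi <- 14 + 8 / (1 + exp(-0.4 * (age - 14)))
      bmi * (h / 100)^2
    },
    bmd_template(age, cfg$bmd_curve_params[[sex]][[metric]]))
  if (!oi) return(base)
  d <- cfg$oi_deficit
  if (!bp || cfg$bp_slope_boost == 0 ||
      !metric %in% c("spine_bmd", "hip_bmd")) return(d * base)
  w <- cfg$bp_effect_window
  pfun <- function(a) switch(metric,
    height = height_template(a, cfg$height_curve_params[[sex]]),
    bmd_template(a, cfg$bmd_curve_params[[sex]][[metric]]))
  lo <- pfun(w[1]); hi <- pfun(w[2])
  below <- d * base
  inwin <- d * pfun(w[1]) + d * (1 + cfg$bp_slope_boost) * (base - lo)
  above <- d * pfun(w[1]) + d * (1 + cfg$bp_slope_boost) * (hi - lo) +
    d * (base - hi)
  ifelse(age <= w[1], below, ifelse(age <= w[2], inwin, above))
}

#' Default binary clinical trait list
#'
#' Twenty traits: the clinically named OI features plus anonymous
#' placeholders, used by the trait-matrix simulator.
#' @return character vector of length 20.
#' @export
oi_trait_names <- function() {
  c("flat_feet", "dentinogenesis_imperfecta", "pectus_carinatum",
    "over_sweating", "scoliosis", "pregnancy_screening_abnormality",
    "limb_deformity", "blue_sclera", "hearing_loss", "joint_laxity",
    "basilar_invagination", "fracture_history", "pectus_excavatum",
    "triangular_face", "ligamentous_laxity", "muscle_weakness",
    "easy_bruising", "bone_pain", "kyphosis", "short_stature")
}

cluster_template <- function(cluster, trait_list) {
  n <- length(trait_list)
  idx <- seq_len(n)
  if (cluster == 1L) as.integer(idx %% 3 != 0) else as.integer(idx %% 3 == 0)
}

#' Draw one patient's binary trait vector from a cluster template
#'
#' Cluster 1 is the severe template (about two thirds of traits positive),
#' cluster 2 the milder one; each entry is flipped independently with
#' probability `flip_prob`, so the expected Hamming distance to the
#' template is `flip_prob * length(trait_list)`.
#'
#' @param cluster 1 or 2.
#' @param trait_list character vector of trait names.
#' @param flip_prob flip probability in \[0, 0.5); at 0.5 the clusters are
#'   unidentifiable and an error is raised.
#' @return named integer 0/1 vector.
#' @export
trait_template <- function(cluster, trait_list = oi_trait_names(),
                           flip_prob = 0) {
  if (!cluster %in% c(1L, 2L)) stop("cluster must be 1 or 2", call. = FALSE)
  if (flip_prob < 0 || flip_prob >= 0.5)
    stop("flip_prob must be in [0, 0.5)", call. = FALSE)
  tmpl <- cluster_template(as.integer(cluster), trait_list)
  flips <- stats::rbinom(length(tmpl), 1L, flip_prob)
  stats::setNames(as.integer(xor(tmpl, flips)), trait_list)
}

variant_panel_path <- function() {
  system.file("extdata", "col1_variant_panel.tsv", package = "oigrowth")
}

#' Simulate a full synthetic cohort
#'
#' Generates the four linked tables the analysis pipeline consumes:
#' a longitudinal measurement table (one row per patient, metric and
#' visit), a binary clinical-trait table for the OI-COL1 patients, an
#' HGVS-coded variant table for the same patients, and a ground-truth table
#' carrying each patient's latent cluster, carrier status and trajectory
#' deficit.  Same config (including seed) gives byte-identical tables.
#'
#' @param config a [sim_config()].
#' @return list with data frames `measurements`, `traits`, `variants`,
#'   `truth`; `truth` carries the generating `config` as an attribute.
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_oi + cfg$n_nonoi
    pid <- sprintf("P%04d", seq_len(n))
    oi <- c(rep(TRUE, cfg$n_oi), rep(FALSE, cfg$n_nonoi))
    sex <- ifelse(stats::runif(n) < cfg$sex_ratio, "male", "female")
    grp <- ifelse(!oi, "non-OI",
                  ifelse(stats::runif(n) < cfg$col1_fraction,
                         "OI-COL1", "OI-nonCOL1"))
    bp <- oi & stats::runif(n) < cfg$bp_treated_frac

    nv <- sample(seq(cfg$visit_count_range[1], cfg$visit_count_range[2]),
                 n, replace = TRUE)
    force_two <- stats::runif(n) < cfg$min_two_frac
    nv[force_two & nv < 2L] <- 2L

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      u <- if (oi[i]) stats::rbeta(nv[i], cfg$age_shape[1], cfg$age_shape[2])
           else stats::runif(nv[i])
      ages <- sort(cfg$age_range[1] + diff(cfg$age_range) * u)
      per_metric <- lapply(metric_levels, function(m) {
        mu <- trajectory_value(m, ages, sex[i], oi[i], bp[i], cfg)
        val <- mu + stats::rnorm(nv[i], 0, cfg$noise_sd[[m]])
        data.frame(patient_id = pid[i], sex = sex[i], group = grp[i],
                   age = ages, metric = m, value = pmax(val, 1e-6),
                   bp_treated = bp[i],
                   visit_key = sprintf("V%02d", seq_len(nv[i])),
                   stringsAsFactors = FALSE)
      })
      rows[[i]] <- do.call(rbind, per_metric)
    }
    measurements <- do.call(rbind, rows)
    rownames(measurements) <- NULL

    # variants + latent clusters for the OI-COL1 patients
    col1 <- which(grp == "OI-COL1")
    panel <- utils::read.delim(variant_panel_path(),
                               stringsAsFactors = FALSE)
    mis_panel <- panel[panel$class == "missense", ]
    non_panel <- panel[panel$class != "missense", ]
    missense <- stats::runif(length(col1)) < cfg$missense_fraction
    vidx <- integer(length(col1))
    vidx[missense] <- sample(nrow(mis_panel), sum(missense), replace = TRUE)
    vidx[!missense] <- sample(nrow(non_panel), sum(!missense), replace = TRUE)
    variants <- data.frame(
      patient_id = pid[col1],
      gene = ifelse(missense, mis_panel$gene[vidx],
                    non_panel$gene[vidx]),
      cdna_hgvs = ifelse(missense, mis_panel$cdna_hgvs[vidx],
                         non_panel$cdna_hgvs[vidx]),
      protein_hgvs = ifelse(missense, mis_panel$protein_hgvs[vidx],
                            non_panel$protein_hgvs[vidx]),
      stringsAsFactors = FALSE)

    p1 <- ifelse(missense, cfg$cluster1_prob[["missense"]],
                 cfg$cluster1_prob[["other"]])
    cluster <- ifelse(stats::runif(length(col1)) < p1, 1L, 2L)
    tr <- t(vapply(cluster, function(cl)
      trait_template(cl, oi_trait_names(), cfg$trait_flip_prob),
      integer(length(oi_trait_names()))))
    if (cfg$trait_missing_prob > 0) {
      miss <- matrix(stats::runif(length(tr)) < cfg$trait_missing_prob,
                     nrow = nrow(tr))
      tr[miss] <- NA_integer_
    }
    traits <- data.frame(patient_id = pid[col1], tr,
                         stringsAsFactors = FALSE)
    names(traits) <- c("patient_id", oi_trait_names())

    truth <- data.frame(
      patient_id = pid, sex = sex, group = grp, oi = oi,
      bp_treated = bp,
      deficit = ifelse(oi, cfg$oi_deficit, 1),
      missense = NA, cluster = NA_integer_,
      stringsAsFactors = FALSE)
    truth$missense[col1] <- missense
    truth$cluster[col1] <- cluster
    # expected sign of the BMD response angle for pairs wholly inside /
    # outside the BP window (0 encodes "on-reference")
    truth$expected_bmd_sign_in_window <- ifelse(
      bp & oi, sign(cfg$oi_deficit * (1 + cfg$bp_slope_boost) - 1),
      ifelse(oi, sign(cfg$oi_deficit - 1), 0))
    truth$expected_bmd_sign_outside <- ifelse(oi, sign(cfg$oi_deficit - 1), 0)
    attr(truth, "config") <- cfg

    list(measurements = measurements, traits = traits,
         variants = variants, truth = truth)
  })
}

#' Write the simulated tables to a directory
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_measurements(cohort$measurements, file.path(dir, "measurements.tsv"))
  utils::write.table(cohort$traits, file.path(dir, "traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$variants, file.path(dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
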