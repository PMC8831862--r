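test_that("identical configs give byte-identical cohorts", {
  a <- simulate_cohort(sim_config(n_oi = 20, n_nonoi = 20, seed = 7))
  b <- simulate_cohort(sim_config(n_oi = 20, n_nonoi = 20, seed = 7))
  expect_identical(a, b)
  d <- simulate_cohort(sim_config(n_oi = 20, n_nonoi = 20, seed = 8))
  expect_false(identical(a$measurements, d$measurements))
})

test_that("invalid config fields raise errors naming the field", {
  expect_error(sim_config(sex_ratio = 1.5), "sex_ratio")
  expect_error(sim_config(visit_count_range = c(0L, 4L)),
               "visit_count_range")
  expect_error(sim_config(age_range = c(5, 60)), "age_range")
  expect_error(sim_config(noise_sd = c(height = -1, weight = 1,
                                       spine_bmd = 1, hip_bmd = 1)),
               "noise_sd")
  expect_error(sim_config(oi_deficit = 0), "oi_deficit")
  expect_error(sim_config(trait_flip_prob = 0.6), "trait_flip_prob")
})

test_that("deficit-free noise-free OI values sit on the non-OI templates", {
  cfg <- sim_config(n_oi = 15, n_nonoi = 5, oi_deficit = 1,
                    bp_slope_boost = 0,
                    noise_sd = c(height = 0, weight = 0, spine_bmd = 0,
                                 hip_bmd = 0),
                    seed = 3)
  co <- simulate_cohort(cfg)
  m <- co$measurements
  h <- m[m$metric == "height", ]
  expect_equal(h$value, vapply(seq_len(nrow(h)), function(i)
    height_template(h$age[i], cfg$height_curve_params[[h$sex[i]]]),
    numeric(1)), tolerance = 1e-9)
  for (site in c("spine_bmd", "hip_bmd")) {
    b <- m[m$metric == site, ]
    expect_equal(b$value, vapply(seq_len(nrow(b)), function(i)
      bmd_template(b$age[i], cfg$bmd_curve_params[[b$sex[i]]][[site]]),
      numeric(1)), tolerance = 1e-9)
  }
})

test_that("noise-free growth templates are non-decreasing over [0, 25]", {
  grid <- seq(0, 25, by = 0.05)
  cfg <- sim_config(n_oi = 1, n_nonoi = 1)
  for (s in c("female", "male")) {
    expect_true(all(diff(height_template(grid,
                                         cfg$height_curve_params[[s]])) >= 0))
    for (site in c("spine_bmd", "hip_bmd"))
      expect_true(all(diff(bmd_template(grid,
                                        cfg$bmd_curve_params[[s]][[site]])) >= 0))
  }
})

test_that("BP boost changes BMD accrual inside the window only", {
  base <- list(n_oi = 40, n_nonoi = 5, bp_slope_boost = 1.5,
               noise_sd = c(height = 0, weight = 0, spine_bmd = 0,
                            hip_bmd = 0),
               visit_count_range = c(4L, 6L), seed = 5)
  treated <- simulate_cohort(do.call(sim_config,
                                     c(base, bp_treated_frac = 1)))
  untreated <- simulate_cohort(do.call(sim_config,
                                       c(base, bp_treated_frac = 0)))
  # same seed and RNG consumption: identical patients and scan ages
  expect_identical(treated$measurements$age, untreated$measurements$age)
  w <- sim_config()$bp_effect_window
  for (site in c("spine_bmd", "hip_bmd")) {
    ti <- treated$measurements[treated$measurements$metric == site, ]
    ui <- untreated$measurements[untreated$measurements$metric == site, ]
    for (pid in unique(ti$patient_id[ti$group != "non-OI"])) {
      tp <- ti[ti$patient_id == pid, ]; up <- ui[ui$patient_id == pid, ]
      slope_diff <- diff(tp$value - up$value) / diff(tp$age)
      t1 <- tp$age[-nrow(tp)]; t2 <- tp$age[-1]
      inside <- t1 >= w[1] & t2 <= w[2]
      outside <- t2 <= w[1] | t1 >= w[2]
      expect_true(all(slope_diff[inside] > 0))
      expect_equal(slope_diff[outside], rep(0, sum(outside)),
                   tolerance = 1e-10)
    }
  }
  # height accrual is never boosted
  th <- treated$measurements[treated$measurements$metric == "height", ]
  uh <- untreated$measurements[untreated$measurements$metric == "height", ]
  expect_equal(th$value, uh$value, tolerance = 1e-12)
})

test_that("trait_template reproduces the template and its flip rate", {
  tl <- oi_trait_names()
  expect_identical(unname(trait_template(1, tl, 0)),
                   unname(trait_template(1, tl, 0)))
  t1 <- trait_template(1, tl, 0); t2 <- trait_template(2, tl, 0)
  expect_true(all(t1 + t2 == 1))        # complementary templates
  expect_gt(sum(t1), sum(t2))           # cluster 1 is the severe one
  set.seed(1)
  flips <- replicate(10000,
                     sum(trait_template(1, tl, 0.1) != t1))
  expect_equal(mean(flips), 20 * 0.1, tolerance = 0.05)
  expect_error(trait_template(3, tl, 0.1), "cluster")
  expect_error(trait_template(1, tl, 0.5), "flip_prob")
})

test_that("cohort tables are mutually consistent", {
  co <- simulate_cohort(sim_config(n_oi = 60, n_nonoi = 30, seed = 9))
  col1 <- co$truth$patient_id[co$truth$group == "OI-COL1"]
  expect_identical(sort(co$traits$patient_id), sort(col1))
  expect_identical(sort(co$variants$patient_id), sort(col1))
  expect_true(all(co$measurements$patient_id %in% co$truth$patient_id))
  expect_true(all(co$truth$cluster[co$truth$group == "OI-COL1"] %in% 1:2))
  expect_true(all(is.na(co$truth$cluster[co$truth$group != "OI-COL1"])))
  # missense flag matches the variant panel class
  cls <- classify_variants(co$variants)
  expect_identical(cls$qualitative,
                   co$truth$missense[match(co$variants$patient_id,
                                           co$truth$patient_id)])
})

test_that("written cohort round-trips through the readers", {
  co <- simulate_cohort(sim_config(n_oi = 10, n_nonoi = 10, seed = 4))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  m2 <- read_measurements(file.path(dir, "measurements.tsv"))
  expect_equal(m2, co$measurements, tolerance = 1e-10,
               ignore_attr = TRUE)
  t2 <- read_traits(file.path(dir, "traits.tsv"))
  expect_identical(t2$patient_id, co$traits$patient_id)
  expect_equal(unname(as.matrix(t2[-1])),
               unname(as.matrix(co$traits[-1])))
})
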