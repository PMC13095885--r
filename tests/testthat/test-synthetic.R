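nonoise <- list(model = "additive", sd_mm = c(blade_length = 0, blade_width = 0))

test_that("noise-free generation reproduces model predictions exactly", {
  cfg <- sim_config("sorghum", genotypes = "GA", tln_values = 18,
                    plants_per_tln = 3, noise = nonoise, seed = 4)
  sim <- generate_dataset(cfg)
  expect_identical(nrow(sim$records), 3L * 18L)
  prof <- predict_profile(default_species_params("sorghum"), 18)
  one <- sim$records[sim$records$plant_id == sim$records$plant_id[1], ]
  expect_equal(one$blade_length_mm, prof$length_mm)
  expect_equal(one$blade_width_mm, prof$width_mm)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config("maize", tln_values = 15:17, plants_per_tln = 4,
                    missing_rate = 0.05, seed = 99)
  expect_identical(generate_dataset(cfg)$records, generate_dataset(cfg)$records)
  p1 <- table1_style_panel("pearl_millet", seed = 21)
  p2 <- table1_style_panel("pearl_millet", seed = 21)
  expect_identical(p1, p2)
  f1 <- tempfile(); f2 <- tempfile()
  write_leaf_csv(p1, f1); write_leaf_csv(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("additive noise has the configured spread and is independent across leaves", {
  cfg <- sim_config("maize", genotypes = "G1", tln_values = 15,
                    plants_per_tln = 500,
                    noise = list(model = "additive",
                                 sd_mm = c(blade_length = 30, blade_width = 3)),
                    seed = 13)
  sim <- generate_dataset(cfg)
  prof <- predict_profile(default_species_params("maize"), 15)
  resid <- sim$records$blade_length_mm - prof$length_mm[sim$records$position]
  expect_equal(stats::sd(resid), 30, tolerance = 1.5 / 30)
  # successive residuals within the generated stream are uncorrelated
  expect_lt(abs(stats::cor(resid[-1], resid[-length(resid)])), 0.05)
})

test_that("missing values are deleted at roughly the configured rate", {
  cfg <- sim_config("sorghum", genotypes = "G1", tln_values = 20,
                    plants_per_tln = 250, noise = nonoise,
                    missing_rate = 0.2, seed = 8)
  rec <- generate_dataset(cfg)$records
  expect_equal(mean(is.na(rec$blade_length_mm)), 0.2, tolerance = 0.15)
  expect_true(all(rec$blade_length_mm > 0, na.rm = TRUE))
})

test_that("panel presets stay inside the observed TLN envelopes", {
  for (sp in c("maize", "sorghum", "pearl_millet")) {
    panel <- table1_style_panel(sp, seed = 2)
    rng <- list(maize = c(11, 25), sorghum = c(9, 44),
                pearl_millet = c(11, 27))[[sp]]
    expect_true(all(panel$tln >= rng[1] & panel$tln <= rng[2]))
    # sizes under default noise stay within 3x the observed extremes
    maxlen <- c(maize = 1210, sorghum = 1230, pearl_millet = 1110)[[sp]]
    expect_true(all(panel$blade_length_mm <= 3 * maxlen, na.rm = TRUE))
    expect_true(all(panel$blade_length_mm >= 1, na.rm = TRUE))
  }
  # sorghum panel exercises the second xs segment (TLN above the 20.5 break)
  expect_gt(max(table1_style_panel("sorghum", seed = 2)$tln), 21)
})

test_that("genotype-level perturbation changes cm and L1 but keeps determinism", {
  cfg <- sim_config("maize", genotypes = c("A", "B"), tln_values = 16,
                    plants_per_tln = 1, noise = nonoise,
                    genotype_cv = 0.2, seed = 31)
  sim <- generate_dataset(cfg)
  cmA <- sim$truth$A$traits$blade_length$fixed[["cm"]]
  cmB <- sim$truth$B$traits$blade_length$fixed[["cm"]]
  expect_false(isTRUE(all.equal(cmA, cmB)))
  expect_identical(generate_dataset(cfg)$truth$A$traits$blade_length$fixed,
                   sim$truth$A$traits$blade_length$fixed)
})

test_that("generate-calibrate round trip reproduces the generating profiles", {
  cfg <- sim_config("maize", genotypes = c("G1", "G2"), tln_values = 12:25,
                    plants_per_tln = 1, noise = nonoise, seed = 17)
  sim <- generate_dataset(cfg)
  cal <- suppressWarnings(calibrate_species(sim$records))
  for (tl in c(13, 17, 24)) {
    orig <- predict_profile(default_species_params("maize"), tl)
    back <- predict_profile(cal$params, tl)
    expect_lt(max(abs(back$length_mm / orig$length_mm - 1)), 0.005)
    expect_lt(max(abs(back$width_mm / orig$width_mm - 1)), 0.005)
    expect_lt(max(abs(back$area_mm2 / orig$area_mm2 - 1)), 0.005)
  }
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config("maize", tln_values = 15, seed = NULL),
               "seed is mandatory")
  expect_error(sim_config("maize", tln_values = 15, plants_per_tln = 0,
                          seed = 1), "plants_per_tln")
  expect_error(sim_config("maize", tln_values = 15, missing_rate = 1,
                          seed = 1), "missing_rate")
  cfg <- sim_config("maize", tln_values = 50, seed = 1)
  expect_error(generate_dataset(cfg), "plausibility range")
})
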