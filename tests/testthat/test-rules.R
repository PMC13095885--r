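test_that("linear xs rule reproduces hand arithmetic", {
  rule <- tln_linear_rule(1.10, 0.47)
  expect_equal(xs_from_tln(rule, 17), 1.10 + 0.47 * 17)
  expect_equal(xs_from_tln(rule, 17), 9.09)
  expect_error(xs_from_tln(rule, 1), "tln must be >= 2")
})

test_that("segmented xs rule is continuous at its breakpoint", {
  rule <- tln_segmented_rule(4.64, 0.46, 0.26, 20.5)  # sorghum blade length
  below <- rule$a + rule$b * 20.5
  above <- rule$a + rule$b * 20.5 + rule$c * (20.5 - 20.5)
  expect_identical(xs_from_tln(rule, 20.5), below)
  expect_identical(below, above)
  # slope changes across the breakpoint
  expect_equal(xs_from_tln(rule, 21) - xs_from_tln(rule, 20),
               rule$b * 0.5 + rule$c * 0.5)
  expect_warning(xs_from_tln(tln_linear_rule(10, 0.5), 5), "inconsistent")
})

test_that("plateau dr rule declines then stays constant", {
  rule <- tln_plateau_rule(2.88, -0.13, 17.63)  # maize blade length
  expect_equal(dr_from_tln(rule, 17), 2.88 - 0.13 * 17)
  expect_equal(dr_from_tln(rule, 17), 0.67)
  bp <- rule$bp
  expect_equal(rule$a + rule$b * bp, dr_from_tln(rule, bp))
  expect_identical(dr_from_tln(rule, bp + 10), dr_from_tln(rule, bp + 1))
  expect_error(tln_plateau_rule(2.88, 0.13, 17.63), "slope must be negative")
  expect_error(tln_plateau_rule(1, -0.2, 17), "plateau value")
})

test_that("TLN rules are continuous at breakpoints to machine precision", {
  seg <- tln_segmented_rule(4.64, 0.46, 0.26, 20.5)
  pla <- tln_plateau_rule(2.88, -0.13, 17.63)
  for (eps in 10^-(6:12)) {
    expect_equal(xs_from_tln(seg, 20.5 - eps), xs_from_tln(seg, 20.5 + eps),
                 tolerance = 1e-5)
    expect_equal(dr_from_tln(pla, 17.63 - eps), dr_from_tln(pla, 17.63 + eps),
                 tolerance = 1e-5)
  }
})

test_that("build_params assembles fixed and TLN-driven parameters", {
  set <- default_species_params("maize")
  p <- build_params(set, "blade_length", 17)
  expect_equal(p$xs, 9.09)
  expect_equal(p$dr, 0.67)
  expect_equal(p$cm, 123.84)
  expect_equal(p$L1, 51.18)
  # sorghum width xs step changes slope across the 20.5 breakpoint
  sset <- default_species_params("sorghum")
  x20 <- build_params(sset, "blade_width", 20)$xs
  x21 <- build_params(sset, "blade_width", 21)$xs
  expect_equal(x21 - x20, 0.25 * 0.5 + 0.20 * 0.5)
  expect_error(build_params(set, "blade_length", 1), "plausibility range")
  expect_error(build_params(set, "blade_length", 50), "plausibility range")
})

test_that("packaged parameter sets round-trip through YAML bit-exactly", {
  set <- default_species_params("sorghum")
  f <- tempfile(fileext = ".yaml")
  write_species_params(set, f)
  back <- read_species_params(f, "sorghum")
  for (tr in c("blade_length", "blade_width")) {
    expect_identical(back$traits[[tr]]$fixed, set$traits[[tr]]$fixed)
    expect_identical(back$traits[[tr]]$se, set$traits[[tr]]$se)
    expect_identical(unclass(back$traits[[tr]]$xs_rule)[c("a", "b", "c", "bp")],
                     unclass(set$traits[[tr]]$xs_rule)[c("a", "b", "c", "bp")])
    expect_identical(unclass(back$traits[[tr]]$dr_rule)[c("a", "b", "bp")],
                     unclass(set$traits[[tr]]$dr_rule)[c("a", "b", "bp")])
  }
  expect_identical(back$shape_factors, c(standard = 0.71, flag = 0.635))
  unlink(f)
})

test_that("packaged defaults carry the published species-generic values", {
  m <- default_species_params("maize")
  expect_identical(m$traits$blade_length$fixed[["cm"]], 123.84)
  expect_identical(m$traits$blade_length$fixed[["L1"]], 51.18)
  s <- default_species_params("sorghum")
  expect_identical(s$traits$blade_length$xs_rule$bp, 20.5)
  expect_identical(s$traits$blade_width$fixed[["L1"]], 4.2)
  pm <- default_species_params("pearl_millet")
  expect_identical(pm$traits$blade_width$fixed[["tb"]], 14.79)
})
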