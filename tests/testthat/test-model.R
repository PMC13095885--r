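# frozen maize blade-length parameters at TLN 17 (generic set):
# xs = 1.10 + 0.47*17, dr = 2.88 - 0.13*17
maize_len_17 <- profile_params(L1 = 51.18, cm = 123.84, rm = 1.17,
                               tb = 2.02, xs = 9.09, dr = 0.67, dsl = 12.53)

test_that("expolinear term matches its closed forms and frozen oracle values", {
  p <- maize_len_17
  # exponent exactly zero at x = tb + 1
  expect_equal(expolinear_value(p$tb + 1, p), p$L1 + (p$cm / p$rm) * log(2))
  # lower asymptote is L1
  expect_equal(expolinear_value(-1e3, p), p$L1, tolerance = 1e-12)
  # frozen high-precision evaluations
  expect_equal(expolinear_value(9.09, p), 802.9759325317, tolerance = 1e-9)
  expect_equal(expolinear_value(9, p), 791.8400036423, tolerance = 1e-9)
})

test_that("y_max is the expolinear value at xs", {
  for (p in random_profile_params(25, seed = 11))
    expect_identical(y_max(p), expolinear_value(p$xs, p))
  expect_equal(y_max(maize_len_17), 802.9759325317, tolerance = 1e-9)
})

test_that("logistic term equals Ymax at xs, decays to zero, and handles dsl = 0", {
  p <- maize_len_17
  expect_equal(logistic_value(p$xs, p), y_max(p))
  expect_equal(logistic_value(17, p), 197.6884116835, tolerance = 1e-9)
  expect_equal(logistic_value(10, p), 792.7459502168, tolerance = 1e-9)
  expect_lt(logistic_value(1e4, p), 1e-6)
  flat <- profile_params(p$L1, p$cm, p$rm, p$tb, p$xs, dr = 1.2, dsl = 0)
  expect_equal(logistic_value(c(p$xs, p$xs + 5, p$xs + 40), flat),
               rep(y_max(flat), 3))
})

test_that("piecewise profile is continuous at xs and peaks there", {
  for (p in random_profile_params(50, seed = 3)) {
    expect_equal(expolinear_value(p$xs, p), logistic_value(p$xs, p),
                 tolerance = 1e-12)
    expect_identical(leaf_dimension(p$xs, p), logistic_value(p$xs, p))
  }
  p <- maize_len_17
  vals <- leaf_dimension(1:17, p)
  expect_true(all(vals < y_max(p)))
  # largest integer-position value lies within one leaf of xs = 9.09
  expect_equal(which.max(vals), 10)
  expect_lte(abs(which.max(vals) - p$xs), 1)
  expect_error(leaf_dimension(0.5, p), "x must be >= 1")
})

test_that("parameter-domain violations are rejected by name", {
  expect_error(profile_params(-1, 10, 1, 2, 8, 0.5, 1), "L1 > 0")
  expect_error(profile_params(10, 0, 1, 2, 8, 0.5, 1), "cm > 0")
  expect_error(profile_params(10, 10, -1, 2, 8, 0.5, 1), "rm > 0")
  expect_error(profile_params(10, 10, 1, 2, 0.9, 0.5, 1), "xs > 1")
  expect_error(profile_params(10, 10, 1, 2, 8, -0.5, 1), "dr >= 0")
  expect_error(profile_params(10, 10, 1, 2, 8, 0.5, -1), "dsl >= 0")
})

test_that("expolinear is stable far into the linear regime (softplus form)", {
  p <- profile_params(L1 = 20, cm = 100, rm = 10, tb = 2, xs = 50,
                      dr = 0.5, dsl = 5)
  # exponent rm*(x - tb - 1) up to 1e4: finite, and slope equals cm
  x <- p$tb + 1 + c(1e2, 1e3, 1e4) / p$rm
  v <- expolinear_value(x, p)
  expect_true(all(is.finite(v)))
  slope <- diff(expolinear_value(c(1e3 - 0.5, 1e3 + 0.5), p))
  expect_equal(slope, p$cm, tolerance = 1e-9)
})

test_that("bell-shaped baseline has its documented closed forms", {
  bp <- bell_params(Y0 = 4000, x0 = 9, a = -0.02, b = 0.001)
  expect_equal(bell_leaf_area(9, bp), 4000)
  sym <- bell_params(Y0 = 1, x0 = 9, a = -0.01, b = 0)
  expect_equal(bell_leaf_area(9 + 4, sym), bell_leaf_area(9 - 4, sym))
  expect_equal(bell_leaf_area(19, sym), exp(-1))
  expect_error(bell_params(-1, 9, -0.01, 0), "Y0")
})

test_that("leaf area applies the ordinary and flag-leaf shape factors", {
  set <- default_species_params("maize")
  expect_identical(leaf_area(100, 50, FALSE, set), 3550)
  expect_identical(leaf_area(100, 50, TRUE, set), 3175)
  expect_identical(leaf_area(0, 123, FALSE, set), 0)
  expect_error(leaf_area(-1, 5, FALSE, set), "must be >= 0")
})

test_that("predicted profiles have tln positive entries with area composed per leaf", {
  for (sp in c("maize", "sorghum", "pearl_millet")) {
    set <- default_species_params(sp)
    prof <- predict_profile(set, 18)
    expect_identical(nrow(prof), 18L)
    expect_true(all(prof$length_mm > 0 & prof$width_mm > 0 & prof$area_mm2 > 0))
    expect_identical(which(prof$is_flag), 18L)
    # flag leaf carries the 0.635 factor, all others 0.71
    expect_equal(prof$area_mm2[18], prof$length_mm[18] * prof$width_mm[18] * 0.635)
    expect_equal(prof$area_mm2[-18],
                 prof$length_mm[-18] * prof$width_mm[-18] * 0.71)
    # loop-free recomputation of the total area
    expect_equal(sum(prof$area_mm2),
                 0.71 * sum(prof$length_mm * prof$width_mm) +
                   (0.635 - 0.71) * prof$length_mm[18] * prof$width_mm[18])
    # the largest leaf sits within one position of the trait's xs
    xs <- xs_from_tln(set$traits$blade_length$xs_rule, 18)
    expect_lte(abs(which.max(prof$length_mm) - xs), 1)
  }
})
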