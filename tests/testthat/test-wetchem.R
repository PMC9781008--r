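test_that("calibration fitting recovers exact lines and the ICH limits", {
  lv <- rep(c(5, 10, 20, 40, 80), each = 3)
  cc <- fitCalibrationCurve(lv, 88.68 * lv - 0.06, blanks = rep(0.2, 6))
  expect_equal(cc@slope, 88.68, tolerance = 1e-10)
  expect_equal(cc@intercept, -0.06, tolerance = 1e-10)
  expect_equal(cc@sigma, 0)
  expect_equal(lod(cc), 0)
  # sigma = 1, S = 3.3 -> LOD = 1 ug/mL = 1000 ng/mL, LOQ = 3030.3... ng/mL
  set.seed(1)
  blanks <- c(-1, 1, -1, 1, -1, 1) / sqrt(1.2)  # sample sd exactly 1
  expect_equal(sd(blanks), 1, tolerance = 1e-12)
  cc2 <- fitCalibrationCurve(lv, 3.3 * lv, blanks = blanks)
  expect_equal(lod(cc2), 1000, tolerance = 1e-9)
  expect_equal(loq(cc2), 1000 * 10 / 3.3, tolerance = 1e-9)
  expect_equal(loq(cc2) / lod(cc2), 10 / 3.3, tolerance = 1e-12)
  expect_error(fitCalibrationCurve(lv, -2 * lv, blanks = rep(0, 6)), "slope")
  expect_error(fitCalibrationCurve(c(1, 2), c(1, 2), rep(0, 6)), "levels")
})

test_that("published detection limits imply the published quantification limits", {
  # LOQ = LOD * 10 / 3.3, printed to two decimals
  lods <- c(CGA = 3.52, nCGA = 2.82, rutin = 4.07)
  expect_equal(round(loqFromLod(lods), 2),
               c(CGA = 10.67, nCGA = 8.55, rutin = 12.33))
})

test_that("recovery percentage follows the spike arithmetic", {
  expect_equal(as.numeric(recoveryPercent(10.85, 2, 8.85)), 100)
  expect_equal(as.numeric(recoveryPercent(2, 2, 8.85)), 0)
  r <- recoveryPercent(10, 2, 8.85)
  expect_equal(as.numeric(r), 100 * 8 / 8.85, tolerance = 1e-12)
  expect_equal(round(as.numeric(r), 1), 90.4)
  expect_false(attr(r, "suspect"))
  expect_true(attr(recoveryPercent(20, 2, 8.85), "suspect"))
  expect_error(recoveryPercent(1, 1, 0), "added")
})

test_that("%RSD follows its formula and is scale invariant", {
  expect_equal(rsdPercent(c(1, 1, 1)), 0)
  expect_equal(rsdPercent(c(9, 11)), 100 * sqrt(2) / 10, tolerance = 1e-12)
  set.seed(2)
  x <- runif(6, 5, 10)
  expect_equal(rsdPercent(3.7 * x), rsdPercent(x), tolerance = 1e-12)
  expect_error(rsdPercent(c(-1, 1)), "zero mean")
  expect_error(rsdPercent(5), "2 replicate")
})

test_that("DPPH inhibition is blank-relative and clipped", {
  expect_equal(dpphInhibition(1, 1), 0)
  expect_equal(dpphInhibition(1, 0), 100)
  expect_equal(dpphInhibition(1, 0.25), 75)
  clipped <- dpphInhibition(1, -0.5)
  expect_equal(as.numeric(clipped), 100)
  expect_true(attr(clipped, "clipped"))
  expect_error(dpphInhibition(0, 0.5), "blank")
})

test_that("EC50 interpolation brackets 50% and ignores redundant points", {
  expect_equal(ec50(ec50FromCurve(c(1, 3), c(25, 75))), 2)
  expect_equal(ec50(ec50FromCurve(c(1, 2, 3), c(25, 50, 75))), 2)
  # appending points outside the bracketing pair changes nothing
  base <- ec50(ec50FromCurve(c(1, 3), c(25, 75)))
  more <- ec50(ec50FromCurve(c(0.1, 1, 3, 30), c(2, 25, 75, 99)))
  expect_equal(more, base, tolerance = 1e-12)
  expect_error(ec50FromCurve(c(1, 2), c(10, 20)), "outside measured range")
})

test_that("the generator round-trip recovers a known EC50 within 2%", {
  tab <- generateDoseResponse(2, hill = 1, noiseSd = 0)  # default 8-point grid
  expect_equal(nrow(tab), 8L)
  got <- ec50(ec50FromCurve(tab$concentration, tab$inhibition))
  expect_lt(abs(got - 2) / 2, 0.02)
})

test_that("content and intake conversions are exact arithmetic", {
  expect_equal(contentPerGram(10, 15, 0.5), 300)
  expect_equal(contentPerGram(10, 15, 1), 150)  # doubling mass halves content
  expect_equal(contentPerGram(0, 15, 0.5), 0)
  expect_error(contentPerGram(1, 15, 0), "positive")
  # 1 ug/g in 0.5 g units, 6/day -> 3 ug/day -> 0.01% of 30 mg
  expect_equal(rdiCoverage(1, 0.5, 6), 0.01)
  # the strongest tea: 992.314 ug/g at 2 g/day covers 6.615% of the RDI
  expect_equal(round(rdiCoverage(992.314, 2, 1), 3), 6.615)
  # scaling content and RDI together cancels
  expect_equal(rdiCoverage(50, 1, 2, rdiMg = 30),
               rdiCoverage(500, 1, 2, rdiMg = 300), tolerance = 1e-12)
  # unit round trip: ug/g -> mg/day -> ug/g
  mgPerDay <- 992.314 * 2 * 1 / 1000
  expect_equal(mgPerDay * 1000 / (2 * 1), 992.314, tolerance = 1e-12)
  expect_error(rdiCoverage(1, 1, 1, rdiMg = 0), "rdiMg")
})

test_that("the validation summary table mirrors the standard row layout", {
  lv <- rep(c(5, 10, 20, 40), each = 3)
  cc <- fitCalibrationCurve(lv, 44.56 * lv - 0.17, blanks = rep(0.05, 6))
  tab <- validationSummaryTable(list(CGA = cc), recovery = c(CGA = 96.2),
                                rsd = c(CGA = 5.6))
  expect_identical(rownames(tab)[1], "range_ug_mL")
  expect_identical(tab["equation", "CGA"], "y = 44.56x -0.17")
  expect_identical(tab["recovery_pct", "CGA"], "96.2")
})
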