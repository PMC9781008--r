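test_that("band profiles evaluate to their defining closed forms", {
  grid <- seq(1000, 1300, by = 2)
  comp <- componentSpec("x", list(bandSpec(1150, 20, 1)))
  spec <- renderComponent(comp, grid)
  expect_equal(spec[grid == 1150], 1)            # peak maximum = height
  expect_equal(spec[grid == 1170], 0.5)          # half-maximum at c + w
  lor <- componentSpec("x", list(bandSpec(1150, 20, 2, "lorentzian")))
  specL <- renderComponent(lor, grid)
  expect_equal(specL[grid == 1150], 2)
  expect_equal(specL[grid == 1170], 1)           # Lorentzian HWHM too
  # two bands sum
  two <- componentSpec("x", list(bandSpec(1100, 10, 1), bandSpec(1200, 10, 1)))
  expect_equal(
    renderComponent(two, grid),
    renderComponent(componentSpec("a", list(bandSpec(1100, 10, 1))), grid) +
      renderComponent(componentSpec("b", list(bandSpec(1200, 10, 1))), grid)
  )
})

test_that("render errors: empty grid, non-monotone grid, band off grid", {
  comp <- componentSpec("x", list(bandSpec(1150, 20, 1)))
  expect_error(renderComponent(comp, numeric()), "empty")
  expect_error(renderComponent(comp, c(1000, 1200, 1100)), "monotone")
  expect_error(
    renderComponent(componentSpec("dnj", list(bandSpec(500, 20, 1))),
                    seq(1000, 1300, 2)),
    "500.*dnj|dnj.*500"
  )
})

test_that("band and component constructors enforce their invariants", {
  expect_error(bandSpec(1000, 0, 1), "width")
  expect_error(bandSpec(1000, 10, -1), "height")
  expect_error(componentSpec("x", list()), "at least one band")
  expect_error(simulationConfig(concLow = 5, concHigh = 5), "concLow")
  expect_error(simulationConfig(gridStart = 4000, gridEnd = 750), "gridStart")
})

test_that("generated dataset has the study layout and is seed-deterministic", {
  cfg <- simulationConfig(seed = 42)
  ds1 <- generateDataset(cfg)
  ds2 <- generateDataset(cfg)
  expect_equal(nSpectra(ds1), 57L)  # 19 products x 3 replicates
  expect_identical(absorbance(ds1), absorbance(ds2))
  expect_identical(sampleData(ds1), sampleData(ds2))
  # different seed changes the data
  ds3 <- generateDataset(simulationConfig(seed = 43))
  expect_false(identical(absorbance(ds1), absorbance(ds3)))
  # replicates share the product's true concentration
  meta <- sampleData(ds1)
  spread <- tapply(meta$concentration, meta$product_id, function(x) {
    diff(range(x))
  })
  expect_true(all(spread == 0))
  expect_error(generateDataset(cfg, components = list()), "component")
})

test_that("noise-free mixtures are exactly bilinear (rank <= #components)", {
  cfg <- simulationConfig(
    nProducts = 8, noiseSd = 0, baselineAmplitude = 0, scatterSd = 0,
    seed = 5
  )
  ds <- generateDataset(cfg)
  expect_lte(qr(absorbance(ds))$rank, 2L)
})

test_that("HPLC calibration simulator reproduces its line when noiseless", {
  tab <- generateHplcCalibration(sigmaBlank = 0, seed = 9)
  fit <- lm(area ~ concentration, data = tab[!tab$is_blank, ])
  expect_equal(unname(coef(fit)), c(-0.06, 88.68), tolerance = 1e-10)
  expect_equal(sum(tab$is_blank), 6L)
  expect_identical(tab, generateHplcCalibration(sigmaBlank = 0, seed = 9))
  expect_error(generateHplcCalibration(levels = numeric()), "levels")
})

test_that("dose-response simulator follows the logistic", {
  # midpoint: inhibition at c = ec50 is exactly 50%
  tab <- generateDoseResponse(2, hill = 1, concGrid = c(0.5, 2, 6), noiseSd = 0)
  expect_equal(tab$inhibition[tab$concentration == 2], 50)
  # direct evaluation: ec50 = 2, hill = 1, c = 6 -> 100/(1 + 2/6) = 75
  expect_equal(tab$inhibition[tab$concentration == 6], 75)
  # steep curves saturate above the midpoint
  steep <- generateDoseResponse(2, hill = 50, concGrid = c(1, 3), noiseSd = 0)
  expect_gt(steep$inhibition[2], 99.9)
  expect_error(generateDoseResponse(2, concGrid = c(-1, 2)), "positive")
  expect_error(generateDoseResponse(-2), "ec50True")
})
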