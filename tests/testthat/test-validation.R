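# Exact bilinear mixtures: replicate-averaged raw spectra, no baseline or
# scatter to remove, so the analyte signal stays exactly linear in y.
noiselessSet <- function(nProducts = 12, seed = 31) {
  cfg <- simulationConfig(nProducts = nProducts, noiseSd = 0,
                          baselineAmplitude = 0, scatterSd = 0, seed = seed)
  averageReplicates(generateDataset(cfg))
}

test_that("noiseless mixtures validate almost perfectly", {
  prep <- noiselessSet()
  sp <- kennardStone(prep, 9)
  cal <- subsetSamples(prep, calibrationIds(sp))
  tst <- subsetSamples(prep, testIds(sp))
  ev <- evaluateModel(absorbance(cal), sampleData(cal)$concentration,
                      absorbance(tst), sampleData(tst)$concentration, nLv = 2)
  expect_gte(ev$report@r2Cal, 0.999)
  expect_gte(ev$report@r2Cv, 0.999)
  expect_gte(ev$report@r2Pred, 0.999)
})

test_that("degenerate test-set handling: cal as test, and no test at all", {
  prep <- noiselessSet(10)
  X <- absorbance(prep)
  y <- sampleData(prep)$concentration
  ev <- evaluateModel(X, y, X, y, nLv = 2)
  expect_equal(ev$report@r2Pred, ev$report@r2Cal, tolerance = 1e-12)
  expect_equal(ev$report@rmsePred, ev$report@rmseCal, tolerance = 1e-12)
  expect_message(ev2 <- evaluateModel(X, y, nLv = 2), "no test set")
  expect_true(is.na(ev2$report@r2Pred))
})

test_that("validation reports serialize and reload losslessly", {
  prep <- noiselessSet(10)
  X <- absorbance(prep)
  y <- sampleData(prep)$concentration
  ev <- evaluateModel(X, y, X, y, nLv = 2)
  f <- withr::local_tempfile(fileext = ".txt")
  writeValidationReport(ev$report, f)
  back <- readValidationReport(f)
  for (s in c("r2Cal", "rmseCal", "r2Cv", "rmseCv", "r2Pred", "rmsePred")) {
    expect_equal(slot(back, s), slot(ev$report, s), tolerance = 1e-15)
  }
})

test_that("Y-randomization separates signal from noise", {
  prep <- noiselessSet(14, seed = 32)
  # keep a manageable variable count for the permutation refits
  idx <- variableIndices(resolveIntervals(wavenumbers(prep),
                                          dnjIntervalPreset()))
  X <- absorbance(prep)[, idx]
  y <- sampleData(prep)$concentration
  yr <- yRandomization(X, y, nPermutations = 25, nLv = 2, seed = 1)
  expect_true(all(yr@passed))
  expect_length(yr@permutedR2cv, 25L)
  # the empirical p-value is bounded below by 1/(n+1)
  expect_gte(yr@pRandT, 1 / 26)
  # identical seeds reproduce the report exactly
  yr2 <- yRandomization(X, y, nPermutations = 25, nLv = 2, seed = 1)
  expect_identical(yr@permutedR2cv, yr2@permutedR2cv)
  # a response unrelated to X is not declared significant
  set.seed(33)
  yNoise <- rnorm(length(y))
  yrN <- yRandomization(X, yNoise, nPermutations = 25, nLv = 2, seed = 2)
  expect_gt(yrN@pRandT, 0.05)
  expect_error(yRandomization(X, rep(1, length(y)), 25, 2), "variance")
  expect_error(yRandomization(X, y, 5, 2), "20")
})

test_that("leverages obey the trace identity and symmetry properties", {
  prep <- noiselessSet(12, seed = 34)
  X <- absorbance(prep)
  y <- sampleData(prep)$concentration
  m <- fitPls(X, y, 2)
  ad <- applicabilityDomain(m, X, y)
  expect_equal(sum(ad@leverages), nLv(m) + 1, tolerance = 1e-8)
  expect_equal(ad@warningLeverage, 3 * (nLv(m) + 1) / nrow(X))
  # duplicated calibration sample -> identical leverages for the pair
  Xd <- rbind(X, X[1, ])
  yd <- c(y, y[1])
  md <- fitPls(Xd, yd, 2)
  add <- applicabilityDomain(md, Xd, yd)
  expect_equal(add@leverages[1], add@leverages[nrow(Xd)], tolerance = 1e-10)
  # a query equal to the calibration mean has leverage 1/n
  adq <- applicabilityDomain(m, X, y, Xquery = colMeans(X))
  expect_equal(adq@leverages[length(adq@leverages)], 1 / nrow(X),
               tolerance = 1e-10)
  expect_false(adq@isCalibration[length(adq@leverages)])
})

test_that("Williams plot renders to file", {
  prep <- noiselessSet(10, seed = 35)
  X <- absorbance(prep)
  y <- sampleData(prep)$concentration
  m <- fitPls(X, y, 2)
  ad <- applicabilityDomain(m, X, y)
  f <- withr::local_tempfile(fileext = ".png")
  plotWilliams(ad, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
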