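test_that("candidate windows tile the grid with the documented arithmetic", {
  grid <- seq_len(100)
  w <- makeIntervals(grid, 30, 10)
  starts <- vapply(w, min, integer(1))
  expect_identical(starts, seq(1L, 71L, by = 10L))  # 8 windows
  expect_length(w, 8L)
  expect_true(all(lengths(w) == 30L))
  expect_identical(sort(unique(unlist(w))), grid)   # full coverage
  # consecutive starts differ by the step
  expect_true(all(diff(starts) == 10L))
  # a final anchored window appears when the stride misses the end
  w2 <- makeIntervals(seq_len(95), 30, 10)
  expect_identical(max(vapply(w2, max, integer(1))), 95L)
  # oversized window collapses to the full range
  expect_identical(makeIntervals(seq_len(20), 30, 10), list(1:20))
})

test_that("named ranges resolve, merge and validate", {
  grid <- seq(750, 4000, by = 3.2)
  iv <- resolveIntervals(grid, dnjIntervalPreset())
  idx <- variableIndices(iv)
  # three disjoint blocks of ~30 variables each
  blocks <- split(idx, cumsum(c(1, diff(idx) != 1)))
  expect_length(blocks, 3L)
  expect_true(all(abs(lengths(blocks) - 30) <= 1))
  expect_true(all(grid[idx] >= 1101 & grid[idx] <= 1697))
  expect_error(resolveIntervals(grid, list(c(100, 200))), "outside")
  # touching ranges merge into deduplicated indices
  merged <- resolveIntervals(grid, list(c(1000, 1100), c(1100, 1200)))
  expect_false(anyDuplicated(variableIndices(merged)) > 0)
  expect_identical(variableIndices(merged),
                   variableIndices(resolveIntervals(grid, list(c(1000, 1200)))))
})

test_that("forward selection finds an informative band and audits itself", {
  # one informative analyte band at 1101-1196; distractor elsewhere
  cfg <- simulationConfig(nProducts = 24, gridStart = 900, gridEnd = 2000,
                          noiseSd = 0.003, seed = 21)
  comps <- list(
    componentSpec("DNJ", list(bandSpec(1150, 20, 1e-3))),
    componentSpec("matrix", list(bandSpec(1700, 40, 0.4)),
                  concRange = c(0.8, 1.2))
  )
  ds <- generateDataset(cfg, comps)
  prep <- preprocessPipeline(ds)
  X <- absorbance(prep)
  y <- sampleData(prep)$concentration
  wn <- wavenumbers(prep)
  cand <- makeIntervals(wn, 30, 10)
  sel <- forwardIpls(X, y, cand, nLv = 4, grid = wn)
  r <- intervalRanges(sel$intervals)
  overlaps <- any(r[, "start"] <= 1196 & r[, "end"] >= 1101)
  expect_true(overlaps)
  # greedy audit: accepted rounds have non-increasing RMSE_CV
  acc <- sel$history$rmseCv[sel$history$accepted]
  expect_true(all(diff(acc) <= 0))
  expect_error(forwardIpls(X, y, list(), nLv = 2), "candidate")
})

test_that("a single full-spectrum candidate reduces to ordinary PLS", {
  set.seed(22)
  X <- matrix(rnorm(18 * 40), nrow = 18)
  y <- drop(X[, 1:5] %*% runif(5, 1, 2)) + rnorm(18, sd = 0.1)
  sel <- forwardIpls(X, y, list(seq_len(40)), nLv = 3)
  expect_identical(variableIndices(sel$intervals), 1:40)
  expect_equal(sel$metrics$rmse, looCv(X, y, 3)$rmse, tolerance = 1e-12)
})

test_that("the window cap terminates the selection", {
  set.seed(23)
  X <- matrix(rnorm(15 * 60), nrow = 15)
  y <- drop(X[, 11:20] %*% runif(10)) + rnorm(15, sd = 0.05)
  cand <- makeIntervals(seq_len(60), 10, 10)
  sel <- forwardIpls(X, y, cand, maxIntervals = 3, nLv = 3,
                     relImprovement = 0)
  expect_lte(nrow(intervalRanges(sel$intervals)), 3L)
})

test_that("interval sets serialize and reload", {
  grid <- seq(750, 4000, by = 3.2)
  iv <- resolveIntervals(grid, dnjIntervalPreset())
  f <- withr::local_tempfile(fileext = ".tsv")
  writeIntervalSet(iv, f)
  back <- readIntervalSet(f, grid)
  expect_identical(variableIndices(back), variableIndices(iv))
})
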