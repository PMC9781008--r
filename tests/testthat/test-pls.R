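test_that("a rank-1 problem is solved exactly with one latent variable", {
  set.seed(1)
  y <- runif(12, 10, 100)
  v <- runif(6, 0.5, 2)
  X <- outer(y, v)          # every column proportional to y
  m <- fitPls(X, y, 1)
  fit <- computeMetrics(y, predict(m, X))
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_lt(fit$rmse, 1e-6)
})

test_that("full-rank PLS with all components equals OLS", {
  set.seed(2)
  X <- matrix(rnorm(12 * 10), nrow = 12)
  y <- rnorm(12)
  m <- fitPls(X, y, min(nrow(X) - 1L, ncol(X)))
  expect_equal(predict(m, X), olsPredict(X, y, X), tolerance = 1e-8)
})

test_that("predictions match the deflation-free Krylov reference, k = 1..5", {
  set.seed(3)
  X <- matrix(rnorm(12 * 10), nrow = 12)
  y <- drop(X %*% rnorm(10)) + rnorm(12, sd = 0.3)
  Xnew <- matrix(rnorm(5 * 10), nrow = 5)
  for (k in 1:5) {
    m <- fitPls(X, y, k)
    expect_equal(predict(m, Xnew), plsKrylovPredict(X, y, k, Xnew),
                 tolerance = 1e-8, label = sprintf("k = %d", k))
  }
})

test_that("model invariants: score orthogonality, RMSE monotone in nLv", {
  set.seed(4)
  X <- matrix(rnorm(20 * 15), nrow = 20)
  y <- drop(X %*% rnorm(15)) + rnorm(20)
  rmse <- vapply(1:8, function(k) {
    m <- fitPls(X, y, k)
    tt <- crossprod(scores(m))
    expect_lt(max(abs(tt - diag(diag(tt), nrow = k))), 1e-8)
    computeMetrics(y, predict(m, X))$rmse
  }, numeric(1))
  expect_true(all(diff(rmse) <= 1e-10))
  expect_error(fitPls(X, y, 16), "nLv")
  expect_error(fitPls(X, rep(1, 20), 2), "variance")
})

test_that("prediction behaves like a centred linear model", {
  set.seed(5)
  X <- matrix(rnorm(15 * 8), nrow = 15)
  y <- drop(X %*% rnorm(8)) + rnorm(15)
  m <- fitPls(X, y, 3)
  # the calibration-mean spectrum predicts the mean response
  expect_equal(drop(predict(m, colMeans(X))), mean(y), tolerance = 1e-10)
  expect_error(predict(m, matrix(0, 2, 5)), "mismatch")
})

test_that("metrics follow their defining formulas", {
  expect_equal(computeMetrics(c(1, 3), c(2, 2))$rmse, 1)  # residuals +1/-1
  y <- c(1, 2, 3, 5)
  perfect <- computeMetrics(y, y)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(computeMetrics(y, rep(mean(y), 4))$r2, 0)
  expect_error(computeMetrics(rep(2, 4), c(1, 2, 3, 4)), "constant")
})

test_that("LOO-CV matches an explicit fold loop and is order-invariant", {
  set.seed(6)
  X <- matrix(rnorm(6 * 5), nrow = 6)
  y <- drop(X %*% rnorm(5)) + rnorm(6, sd = 0.2)
  got <- looCv(X, y, 2)
  preds <- vapply(1:6, function(i) {
    predict(fitPls(X[-i, ], y[-i], 2), X[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(got$rmse, sqrt(mean((y - preds)^2)), tolerance = 1e-12)
  perm <- sample(6)
  expect_equal(looCv(X[perm, ], y[perm], 2)$rmse, got$rmse, tolerance = 1e-12)
  expect_error(looCv(X, y, 5), "n - 2")
})

test_that("LOO-CV error vanishes on noiseless rank-1 data", {
  set.seed(7)
  y <- runif(8, 1, 5)
  X <- outer(y, runif(4, 0.5, 2))
  expect_lt(looCv(X, y, 1)$rmse, 1e-6)
})

test_that("latent-variable selection is parsimonious", {
  # pure-noise response: no k meaningfully beats the minimum, pick 1
  set.seed(8)
  Xn <- matrix(rnorm(20 * 10), nrow = 20)
  yn <- rnorm(20)
  expect_equal(selectNLv(Xn, yn, maxLv = 5)$nLv, 1L)
  # 3-component mixture at low noise: selected complexity matches the rank
  set.seed(9)
  C <- matrix(runif(20 * 3), nrow = 20)
  S <- matrix(runif(3 * 30), nrow = 3)
  X <- C %*% S + matrix(rnorm(20 * 30, sd = 0.001), nrow = 20)
  y <- C[, 1]
  k <- selectNLv(X, y, maxLv = 6)$nLv
  expect_gte(k, 2L)
  expect_lte(k, 4L)
})

test_that("model serialization round-trips losslessly", {
  set.seed(10)
  X <- matrix(rnorm(10 * 6), nrow = 10)
  y <- rnorm(10)
  m <- fitPls(X, y, 3, variables = 11:16, wavenumbers = seq(1100, 1120, 4))
  f <- withr::local_tempfile(fileext = ".txt")
  writePlsModel(m, f)
  back <- readPlsModel(f)
  expect_equal(back@regressionVector, m@regressionVector, tolerance = 1e-15)
  expect_equal(back@scores, m@scores, tolerance = 1e-15)
  expect_identical(back@variables, m@variables)
  expect_equal(predict(back, X), predict(m, X), tolerance = 1e-14)
})
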