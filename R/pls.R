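#' Fit a NIPALS PLS1 regression model
#'
#' Variables are autoscaled (column mean 0, sd 1) with parameters fitted on
#' the supplied rows, and the response is mean-centred (not variance-scaled,
#' so RMSEs stay in concentration units). Each latent variable takes the
#' weight `w = X'y / ||X'y||`, score `t = X w`, x-loading `p = X't / (t't)`,
#' y-loading `q = y't / (t't)`, then deflates `X <- X - t p'` and
#' `y <- y - t q`. The regression vector `b = W (P'W)^{-1} q` maps autoscaled
#' spectra to centred predictions.
#'
#' @param X raw (preprocessed, not autoscaled) matrix, samples x variables.
#' @param y reference concentrations, length nrow(X), non-constant.
#' @param nLv number of latent variables,
#'   1 <= nLv <= min(nrow(X) - 1, ncol(X)).
#' @param variables optional integer indices recording which columns of a
#'   larger grid `X` represents (bookkeeping for interval models).
#' @param wavenumbers optional wavenumbers of the modelled variables.
#' @return a [PLSModel-class].
#' @examples
#' X <- matrix(rnorm(60), nrow = 10)
#' y <- X[, 1] + 0.1 * rnorm(10)
#' fitPls(X, y, nLv = 2)
#' @export
fitPls <- function(X, y, nLv, variables = seq_len(ncol(X)),
                   wavenumbers = as.numeric(variables)) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (stats::sd(y) == 0) stop("y has zero variance")
  kMax <- min(n - 1L, p)
  if (nLv < 1L || nLv > kMax) {
    stop(sprintf("nLv must be between 1 and %d", kMax))
  }
  auto <- autoscaleFit(X, wavenumbers)
  Xs <- autoscaleApply(X, auto)
  yCenter <- mean(y)
  yc <- y - yCenter
  W <- matrix(0, p, nLv)
  P <- matrix(0, p, nLv)
  Tm <- matrix(0, n, nLv)
  q <- numeric(nLv)
  Xd <- Xs; yd <- yc
  for (k in seq_len(nLv)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("deflated covariance vanished; reduce nLv")
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    P[, k] <- drop(crossprod(Xd, t)) / tt
    q[k] <- sum(yd * t) / tt
    W[, k] <- w
    Tm[, k] <- t
    Xd <- Xd - tcrossprod(t, P[, k])
    yd <- yd - t * q[k]
  }
  b <- drop(W %*% solve(crossprod(P, W), q))
  methods::new("PLSModel",
    nLv = as.integer(nLv), weights = W, loadings = P, yLoadings = q,
    scores = Tm, regressionVector = b, autoscale = auto,
    yCenter = yCenter, variables = as.integer(variables),
    wavenumbers = wavenumbers
  )
}

#' Predict concentrations from a fitted PLS model
#'
#' Applies the calibration autoscaling parameters to the new spectra and
#' evaluates `scale(Xnew) %*% b + yCenter`.
#'
#' @param object a [PLSModel-class].
#' @param newdata matrix (or single spectrum) on the same variable grid the
#'   model was fitted on.
#' @return numeric vector of predicted concentrations.
#' @export
setMethod("predict", "PLSModel", function(object, newdata) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L)
       else as.matrix(newdata)
  if (ncol(X) != length(object@autoscale$means)) {
    stop(sprintf(
      "variable grid mismatch: model has %d variables, newdata %d",
      length(object@autoscale$means), ncol(X)
    ))
  }
  Xs <- autoscaleApply(X, object@autoscale)
  drop(Xs %*% object@regressionVector) + object@yCenter
})

# Project new (raw) spectra into the model's latent-score space.
projectScores <- function(model, X) {
  Xs <- autoscaleApply(X, model@autoscale)
  R <- model@weights %*% solve(crossprod(model@loadings, model@weights))
  Xs %*% R
}

#' Regression metrics: R2 and RMSE
#'
#' `rmse = sqrt(mean((y - yhat)^2))`;
#' `r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param y observed values (length >= 2, non-constant).
#' @param yHat predictions of the same length.
#' @return list with `r2` and `rmse`.
#' @export
computeMetrics <- function(y, yHat) {
  if (length(y) != length(yHat)) stop("length mismatch")
  if (length(y) < 2L) stop("at least 2 observations are required")
  ss <- sum((y - mean(y))^2)
  if (ss == 0) stop("R2 undefined for a constant y")
  list(
    r2 = 1 - sum((y - yHat)^2) / ss,
    rmse = sqrt(mean((y - yHat)^2))
  )
}

#' Leave-one-out cross-validation of the PLS chain
#'
#' For each held-out sample the full chain (autoscaling and PLS fit) is
#' refitted on the remaining rows and the held-out spectrum predicted.
#' Metrics summarize the n held-out predictions, so the result is invariant
#' to row order.
#'
#' @param X raw (preprocessed) matrix, samples x variables, n >= 3.
#' @param y reference concentrations.
#' @param nLv latent variables; must satisfy nLv <= n - 2 so every fold can
#'   be fitted.
#' @param returnPredictions also return the held-out predictions.
#' @return list with `r2`, `rmse` and optionally `predictions`.
#' @export
looCv <- function(X, y, nLv, returnPredictions = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("LOO cross-validation needs n >= 3")
  if (nLv > n - 2L) stop("nLv must be <= n - 2 for leave-one-out")
  preds <- vapply(seq_len(n), function(i) {
    m <- fitPls(X[-i, , drop = FALSE], y[-i], nLv)
    predict(m, X[i, , drop = FALSE])
  }, numeric(1L))
  out <- computeMetrics(y, preds)
  if (returnPredictions) out$predictions <- preds
  out
}

#' Choose the number of latent variables by the parsimonious near-minimum
#'
#' Computes RMSE_CV for k = 1..maxLv and returns the smallest k whose
#' RMSE_CV lies within 1% (relative) of the global minimum, trading a
#' negligible loss of cross-validated accuracy for a simpler model.
#'
#' @param X raw (preprocessed) matrix.
#' @param y reference concentrations.
#' @param maxLv largest k to consider (capped at min(n - 2, p)).
#' @param relTol relative near-minimum band (default 0.01).
#' @return list with `nLv` (selected), `rmseCv` (per k) and `r2Cv` (per k).
#' @export
selectNLv <- function(X, y, maxLv = 10L, relTol = 0.01) {
  X <- as.matrix(X)
  maxLv <- min(maxLv, nrow(X) - 2L, ncol(X))
  if (maxLv < 1L) stop("no admissible number of latent variables")
  cv <- lapply(seq_len(maxLv), function(k) looCv(X, y, k))
  rmse <- vapply(cv, `[[`, numeric(1L), "rmse")
  r2 <- vapply(cv, `[[`, numeric(1L), "r2")
  k <- which(rmse <= min(rmse) * (1 + relTol))[1L]
  list(nLv = as.integer(k), rmseCv = rmse, r2Cv = r2)
}

#' Serialize a PLS model to structured text, and load it back
#'
#' All matrices and parameters are written in full double precision (17
#' significant digits), so the round trip is lossless to 1e-15.
#'
#' @param model a [PLSModel-class].
#' @param path file path.
#' @return `writePlsModel` returns `path` invisibly; `readPlsModel` the
#'   restored [PLSModel-class].
#' @export
writePlsModel <- function(model, path) {
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  block <- function(name, x) {
    c(sprintf("#block %s %d %d", name, nrow(x), ncol(x)),
      apply(x, 1L, function(r) paste(fmt(r), collapse = " ")))
  }
  vec <- function(name, x) {
    c(sprintf("#vector %s %d", name, length(x)),
      paste(fmt(x), collapse = " "))
  }
  lines <- c(
    "#plsmodel 1",
    sprintf("#nlv %d", model@nLv),
    vec("ycenter", model@yCenter),
    vec("variables", model@variables),
    vec("wavenumbers", model@wavenumbers),
    vec("means", model@autoscale$means),
    vec("sds", model@autoscale$sds),
    vec("yloadings", model@yLoadings),
    vec("regression", model@regressionVector),
    block("weights", model@weights),
    block("loadings", model@loadings),
    block("scores", model@scores)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writePlsModel
#' @export
readPlsModel <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "#plsmodel")) stop("not a PLS model file")
  i <- 2L
  vals <- list()
  while (i <= length(lines)) {
    header <- strsplit(lines[i], " ", fixed = TRUE)[[1L]]
    if (header[1L] == "#nlv") {
      vals$nlv <- as.integer(header[2L]); i <- i + 1L
    } else if (header[1L] == "#vector") {
      vals[[header[2L]]] <- as.numeric(
        strsplit(lines[i + 1L], " ", fixed = TRUE)[[1L]]
      )
      i <- i + 2L
    } else if (header[1L] == "#block") {
      nr <- as.integer(header[3L])
      rows <- lines[(i + 1L):(i + nr)]
      vals[[header[2L]]] <- do.call(rbind, lapply(rows, function(r) {
        as.numeric(strsplit(r, " ", fixed = TRUE)[[1L]])
      }))
      i <- i + 1L + nr
    } else {
      stop("malformed model file at line ", i)
    }
  }
  methods::new("PLSModel",
    nLv = vals$nlv, weights = vals$weights, loadings = vals$loadings,
    yLoadings = vals$yloadings, scores = vals$scores,
    regressionVector = vals$regression,
    autoscale = list(means = vals$means, sds = vals$sds),
    yCenter = vals$ycenter, variables = as.integer(vals$variables),
    wavenumbers = vals$wavenumbers
  )
}
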