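#' Calibration / cross-validation / external-prediction metrics
#'
#' Fits the supplied latent-variable count on the calibration rows, computes
#' calibration metrics on the fitted values, leave-one-out cross-validation
#' metrics, and — when a test set is supplied — external prediction metrics
#' with the calibration model left untouched.
#'
#' @param Xcal,yCal calibration spectra (preprocessed) and responses.
#' @param Xtest,yTest optional external test set on the same variable grid;
#'   when absent the prediction metrics are `NA` and flagged by a message.
#' @param nLv latent variables.
#' @return list with `report` (a [ValidationReport-class]) and `model`
#'   (the calibration [PLSModel-class]).
#' @export
evaluateModel <- function(Xcal, yCal, Xtest = NULL, yTest = NULL, nLv = 6L) {
  Xcal <- as.matrix(Xcal)
  model <- fitPls(Xcal, yCal, nLv)
  cal <- computeMetrics(yCal, predict(model, Xcal))
  cv <- looCv(Xcal, yCal, nLv)
  if (is.null(Xtest) || NROW(Xtest) == 0L) {
    message("no test set supplied; prediction metrics omitted")
    pred <- list(r2 = NA_real_, rmse = NA_real_)
  } else {
    pred <- computeMetrics(yTest, predict(model, as.matrix(Xtest)))
  }
  report <- methods::new("ValidationReport",
    r2Cal = cal$r2, rmseCal = cal$rmse,
    r2Cv = cv$r2, rmseCv = cv$rmse,
    r2Pred = pred$r2, rmsePred = pred$rmse,
    nLv = as.integer(nLv)
  )
  list(report = report, model = model)
}

#' Y-randomization (response permutation) robustness test
#'
#' Refits the full chain (autoscaling + PLS at a fixed latent-variable
#' count) on `nPermutations` multiset-preserving shuffles of the response
#' and records each cross-validated R2. Three significance summaries are
#' computed on the paired differences `d_i = realR2cv - permutedR2cv_i`:
#' a one-sided Wilcoxon signed-rank test, a one-sided sign test, and the
#' empirical randomization p-value
#' `(1 + #\{permuted >= real\}) / (nPermutations + 1)`. Each is "passed" at
#' alpha = 0.05.
#'
#' @param X preprocessed calibration matrix.
#' @param y reference concentrations (non-constant).
#' @param nPermutations number of shuffles (>= 20; 100 is the conventional
#'   full run).
#' @param nLv latent variables used for every refit.
#' @param seed RNG seed for the shuffles.
#' @return a [PermutationReport-class].
#' @export
yRandomization <- function(X, y, nPermutations = 100L, nLv = 6L, seed = 1L) {
  if (stats::sd(y) == 0) stop("y has zero variance")
  if (nPermutations < 20L) stop("nPermutations must be >= 20")
  X <- as.matrix(X)
  real <- looCv(X, y, nLv)$r2
  permuted <- withSeed(seed, {
    vapply(seq_len(nPermutations), function(i) {
      looCv(X, sample(y), nLv)$r2
    }, numeric(1L))
  })
  d <- real - permuted
  pW <- stats::wilcox.test(d, alternative = "greater", exact = FALSE)$p.value
  pS <- stats::binom.test(sum(d > 0), sum(d != 0),
                          alternative = "greater")$p.value
  pR <- (1 + sum(permuted >= real)) / (nPermutations + 1)
  methods::new("PermutationReport",
    nPermutations = as.integer(nPermutations),
    permutedR2cv = permuted, realR2cv = real,
    pWilcoxon = pW, pSign = pS, pRandT = pR,
    passed = c(wilcoxon = pW < 0.05, sign = pS < 0.05, randomization = pR < 0.05)
  )
}

#' Williams-plot applicability domain
#'
#' Leverages are computed in latent-score space:
#' `h_i = 1/n + t_i' (T'T)^{-1} t_i` with `T` the calibration scores (query
#' spectra are projected through the model weights). The warning leverage is
#' `h* = 3 (nLv + 1) / n_cal`. Calibration residuals are studentized as
#' `e_i / (s sqrt(1 - h_i))` with `s` the residual standard deviation on
#' `n - nLv - 1` degrees of freedom; query residuals (when reference values
#' are supplied) use `e / s` since query leverage is not bounded by 1.
#' A sample is outside the domain when `h > h*` or |studentized residual|
#' exceeds 3.
#'
#' @param model a fitted [PLSModel-class].
#' @param Xcal,yCal the calibration data the model was fitted on.
#' @param Xquery optional query spectra on the same grid.
#' @param yQuery optional reference values for the query spectra.
#' @return an [ADReport-class]; calibration rows first, then query rows.
#' @export
applicabilityDomain <- function(model, Xcal, yCal, Xquery = NULL,
                                yQuery = NULL) {
  Xcal <- as.matrix(Xcal)
  Tm <- model@scores
  TtT <- crossprod(Tm)
  if (abs(det(TtT)) < .Machine$double.eps) stop("singular score covariance")
  TtTinv <- solve(TtT)
  n <- nrow(Xcal)
  k <- model@nLv
  hCal <- 1 / n + rowSums((Tm %*% TtTinv) * Tm)
  resCal <- yCal - predict(model, Xcal)
  df <- n - k - 1L
  s <- sqrt(sum(resCal^2) / df)
  stCal <- resCal / (s * sqrt(pmax(1e-12, 1 - hCal)))
  hStar <- 3 * (k + 1) / n
  lev <- hCal; st <- stCal; isCal <- rep(TRUE, n)
  if (!is.null(Xquery) && NROW(Xquery) > 0L) {
    Xquery <- if (is.null(dim(Xquery))) matrix(Xquery, nrow = 1L)
              else as.matrix(Xquery)
    Tq <- projectScores(model, Xquery)
    hQ <- 1 / n + rowSums((Tq %*% TtTinv) * Tq)
    stQ <- if (!is.null(yQuery)) {
      (yQuery - predict(model, Xquery)) / s
    } else rep(NA_real_, nrow(Xquery))
    lev <- c(lev, hQ); st <- c(st, stQ)
    isCal <- c(isCal, rep(FALSE, nrow(Xquery)))
  }
  outside <- (lev > hStar) | (!is.na(st) & abs(st) > 3)
  methods::new("ADReport",
    leverages = lev, warningLeverage = hStar,
    studentizedResiduals = st, outsideDomain = outside,
    isCalibration = isCal
  )
}

#' Draw a Williams plot
#'
#' Leverage on the x-axis, studentized residual on the y-axis, with the
#' warning-leverage and +/-3 residual guide lines. Calibration samples are
#' filled circles, query samples diamonds.
#'
#' @param ad an [ADReport-class].
#' @param file optional PNG path; when given the plot is written there.
#' @param ... further arguments passed to [graphics::plot()].
#' @return the input, invisibly.
#' @export
plotWilliams <- function(ad, file = NULL, ...) {
  draw <- function() {
    lev <- ad@leverages
    st <- ad@studentizedResiduals
    ylim <- range(c(-3.5, 3.5, st), na.rm = TRUE)
    xlim <- range(c(0, ad@warningLeverage * 1.2, lev))
    graphics::plot(lev, st, xlim = xlim, ylim = ylim,
      pch = ifelse(ad@isCalibration, 16L, 18L),
      col = ifelse(ad@outsideDomain, "red3", "grey25"),
      xlab = "Leverage", ylab = "Studentized residual",
      main = "Williams plot", ...)
    graphics::abline(v = ad@warningLeverage, lty = 2)
    graphics::abline(h = c(-3, 3), lty = 3)
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off())
    draw()
  } else {
    draw()
  }
  invisible(ad)
}

#' Serialize / restore a ValidationReport as flat key-value text
#'
#' @param report a [ValidationReport-class].
#' @param path file path.
#' @return `writeValidationReport` returns `path` invisibly;
#'   `readValidationReport` the restored metrics part of the report.
#' @export
writeValidationReport <- function(report, path) {
  fmt <- function(x) format(x, digits = 17, trim = TRUE)
  lines <- c(
    paste("n_lv", report@nLv),
    paste("r2_cal", fmt(report@r2Cal)),
    paste("rmse_cal", fmt(report@rmseCal)),
    paste("r2_cv", fmt(report@r2Cv)),
    paste("rmse_cv", fmt(report@rmseCv)),
    paste("r2_pred", fmt(report@r2Pred)),
    paste("rmse_pred", fmt(report@rmsePred))
  )
  perm <- report@permutation
  if (!is.null(perm)) {
    lines <- c(lines,
      paste("perm_n", perm@nPermutations),
      paste("perm_real_r2cv", fmt(perm@realR2cv)),
      paste("perm_p_wilcoxon", fmt(perm@pWilcoxon)),
      paste("perm_p_sign", fmt(perm@pSign)),
      paste("perm_p_randomization", fmt(perm@pRandT))
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeValidationReport
#' @export
readValidationReport <- function(path) {
  kv <- utils::read.table(path, header = FALSE, sep = " ",
                          col.names = c("key", "value"),
                          colClasses = "character")
  get <- function(k) as.numeric(kv$value[kv$key == k])
  methods::new("ValidationReport",
    r2Cal = get("r2_cal"), rmseCal = get("rmse_cal"),
    r2Cv = get("r2_cv"), rmseCv = get("rmse_cv"),
    r2Pred = get("r2_pred"), rmsePred = get("rmse_pred"),
    nLv = as.integer(get("n_lv"))
  )
}
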