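#' Asymmetric weighted-least-squares baseline removal
#'
#' Fits a polynomial baseline by iteratively reweighted least squares.
#' Points lying above the current baseline (candidate peaks) are
#' down-weighted: residuals r = y - baseline get weight 1 when r <= 0 and
#' exp(-r / sd(r)) otherwise, so the fit tracks the lower envelope of the
#' spectrum. Iteration stops when the weight vector changes by less than
#' `tol` in relative L2 norm, or after `maxIter` iterations.
#'
#' @param wavenumbers wavenumber grid (cm^-1).
#' @param absorbance absorbance vector, same length.
#' @param polyOrder polynomial order (>= 0, < number of points).
#' @param maxIter maximum reweighting iterations (>= 1).
#' @param tol relative L2 convergence tolerance on the weights.
#' @return list with `baseline` and `corrected` (absorbance - baseline).
#' @examples
#' wn <- seq(750, 4000, by = 3.2)
#' y <- 0.1 + 1e-4 * wn + exp(-log(2) * ((wn - 1150) / 10)^2)
#' bl <- wlsBaseline(wn, y, polyOrder = 1)
#' @export
wlsBaseline <- function(wavenumbers, absorbance, polyOrder = 2L,
                        maxIter = 100L, tol = 1e-6) {
  n <- length(absorbance)
  if (length(wavenumbers) != n) stop("wavenumbers/absorbance length mismatch")
  if (polyOrder < 0L || polyOrder >= n) {
    stop("polyOrder must be >= 0 and < number of points")
  }
  if (maxIter < 1L) stop("maxIter must be >= 1")
  tnorm <- if (n > 1L) {
    2 * (wavenumbers - min(wavenumbers)) /
      (max(wavenumbers) - min(wavenumbers)) - 1
  } else 0
  basis <- outer(tnorm, 0:polyOrder, `^`)
  w <- rep(1, n)
  baseline <- numeric(n)
  for (iter in seq_len(maxIter)) {
    fit <- stats::lm.wfit(basis, absorbance, w)
    baseline <- drop(basis %*% fit$coefficients)
    r <- absorbance - baseline
    s <- stats::sd(r)
    if (!is.finite(s) || s == 0) break
    wNew <- ifelse(r <= 0, 1, exp(-r / s))
    if (sqrt(sum((wNew - w)^2)) < tol * sqrt(sum(w^2))) {
      w <- wNew
      break
    }
    w <- wNew
  }
  list(baseline = baseline, corrected = absorbance - baseline)
}

#' Standard normal variate (SNV) scaling of one spectrum
#'
#' Subtracts the spectrum mean and divides by its sample standard deviation
#' (n-1 denominator), removing additive offsets and multiplicative scatter.
#'
#' @param absorbance numeric vector with at least 2 points and nonzero
#'   variance.
#' @return the standardized spectrum (mean 0, sd 1).
#' @examples
#' snv(c(1, 2, 3))  # -1 0 1
#' @export
snv <- function(absorbance) {
  if (length(absorbance) < 2L) stop("SNV needs at least 2 points")
  s <- stats::sd(absorbance)
  if (s == 0) stop("SNV undefined for a zero-variance spectrum")
  (absorbance - mean(absorbance)) / s
}

#' Fit per-variable autoscaling parameters on the calibration rows
#'
#' @param X calibration matrix (samples x variables).
#' @param wavenumbers optional grid, used to name an offending variable in
#'   the zero-variance error.
#' @return list with `means` and `sds` (sample sd, n-1).
#' @export
autoscaleFit <- function(X, wavenumbers = NULL) {
  X <- as.matrix(X)
  means <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  bad <- which(sds == 0)
  if (length(bad)) {
    label <- if (!is.null(wavenumbers)) {
      sprintf("%.1f cm-1", wavenumbers[bad[1L]])
    } else sprintf("column %d", bad[1L])
    stop("zero-variance variable at ", label)
  }
  list(means = means, sds = sds)
}

#' Apply autoscaling parameters to a matrix on the same variable grid
#'
#' @param X matrix (or single row) to scale.
#' @param params parameters from [autoscaleFit()].
#' @return the column-standardized matrix.
#' @export
autoscaleApply <- function(X, params) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != length(params$means)) {
    stop("variable count does not match the autoscaling parameters")
  }
  sweep(sweep(X, 2L, params$means, `-`), 2L, params$sds, `/`)
}

#' Invert autoscaling
#'
#' @param X an autoscaled matrix.
#' @param params parameters from [autoscaleFit()].
#' @return the matrix on the original scale.
#' @export
autoscaleInvert <- function(X, params) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  sweep(sweep(X, 2L, params$sds, `*`), 2L, params$means, `+`)
}

#' Average replicate spectra per product
#'
#' @param ss a [SpectraSet-class] whose metadata has a `product_id` column.
#' @return a [SpectraSet-class] with one mean spectrum per product; the
#'   metadata keeps the first replicate's product-level fields and the
#'   product id becomes the sample id.
#' @export
averageReplicates <- function(ss) {
  meta <- sampleData(ss)
  if (!"product_id" %in% names(meta)) {
    stop("sample metadata lacks a 'product_id' column")
  }
  products <- unique(meta$product_id)
  X <- absorbance(ss)
  avg <- t(vapply(products, function(p) {
    colMeans(X[meta$product_id == p, , drop = FALSE])
  }, numeric(ncol(X))))
  first <- match(products, meta$product_id)
  newMeta <- meta[first, , drop = FALSE]
  newMeta$sample_id <- products
  newMeta$replicate <- NULL
  rownames(newMeta) <- NULL
  spectraSet(wavenumbers(ss), avg, newMeta, processing(ss))
}

#' Preprocessing chain: replicate averaging, baseline removal, SNV
#'
#' Averages replicate spectra per product (so downstream splitting operates
#' on product-level spectra), removes a weighted-least-squares polynomial
#' baseline from each spectrum and applies SNV. Autoscaling is deliberately
#' not applied here: its parameters must be fitted on calibration rows only,
#' which happens inside model fitting. The applied stages are recorded in
#' the dataset's `processing` provenance.
#'
#' @param ss a [SpectraSet-class].
#' @param polyOrder,maxIter,tol baseline parameters, see [wlsBaseline()].
#' @param average average replicates per product first (default TRUE; set
#'   FALSE when the data are already one spectrum per product).
#' @return the preprocessed [SpectraSet-class], provenance
#'   `c("baseline", "snv")`.
#' @export
preprocessPipeline <- function(ss, polyOrder = 2L, maxIter = 100L,
                               tol = 1e-6, average = TRUE) {
  if (average) ss <- averageReplicates(ss)
  wn <- wavenumbers(ss)
  X <- absorbance(ss)
  out <- t(apply(X, 1L, function(y) {
    snv(wlsBaseline(wn, y, polyOrder, maxIter, tol)$corrected)
  }))
  spectraSet(wn, out, sampleData(ss),
             processing = c(processing(ss), "baseline", "snv"))
}
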