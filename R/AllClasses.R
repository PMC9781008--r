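#' @import methods
NULL

#' SpectraSet: wavenumber-indexed absorbance spectra with sample metadata
#'
#' Container for a set of absorbance spectra measured on a common, strictly
#' ascending wavenumber grid. Rows of the absorbance matrix are spectra
#' (samples), columns are wavenumber variables. Per-sample metadata carries
#' the product identity, replicate number, sample role (calibration/test)
#' and the reference analyte concentration used as the regression response.
#'
#' @slot wavenumbers numeric, strictly increasing grid in cm^-1.
#' @slot absorbance numeric matrix, samples x wavenumbers, no missing values.
#' @slot sampleData data.frame with one row per spectrum; must contain a
#'   `sample_id` column (unique) and usually `product_id`, `replicate`,
#'   `concentration` (reference analyte level, e.g. ug/g) and `role`.
#' @slot processing character vector naming the preprocessing stages already
#'   applied, in order (e.g. `c("baseline", "snv")`).
#'
#' @seealso [spectraSet()], [generateDataset()], [preprocessPipeline()]
#' @export
setClass("SpectraSet",
  representation(
    wavenumbers = "numeric",
    absorbance = "matrix",
    sampleData = "data.frame",
    processing = "character"
  ),
  prototype(processing = character())
)

setValidity("SpectraSet", function(object) {
  msg <- character()
  wn <- object@wavenumbers
  ab <- object@absorbance
  sd <- object@sampleData
  if (length(wn) < 1L) msg <- c(msg, "empty wavenumber grid")
  if (length(wn) > 1L && any(diff(wn) <= 0)) {
    msg <- c(msg, "wavenumbers must be strictly increasing")
  }
  if (ncol(ab) != length(wn)) {
    msg <- c(msg, "ncol(absorbance) must equal length(wavenumbers)")
  }
  if (anyNA(ab)) msg <- c(msg, "absorbance contains missing values")
  if (nrow(sd) != nrow(ab)) {
    msg <- c(msg, "sampleData must have one row per spectrum")
  }
  if (!"sample_id" %in% names(sd)) {
    msg <- c(msg, "sampleData must contain a 'sample_id' column")
  } else if (anyDuplicated(sd$sample_id)) {
    dup <- sd$sample_id[duplicated(sd$sample_id)][1L]
    msg <- c(msg, sprintf("duplicate sample id '%s'", dup))
  }
  if (length(msg)) msg else TRUE
})

#' PLSModel: fitted PLS1 calibration model
#'
#' A NIPALS PLS1 regression model fitted on autoscaled spectra against a
#' mean-centred concentration response. The stored autoscaling parameters
#' and response centre allow prediction in the original units.
#'
#' @slot nLv number of latent variables.
#' @slot weights x-weights W (variables x LV), unit norm columns.
#' @slot loadings x-loadings P (variables x LV).
#' @slot yLoadings y-loadings q (length LV).
#' @slot scores calibration score matrix T (samples x LV), columns orthogonal.
#' @slot regressionVector regression coefficients in the autoscaled variable
#'   space; predictions are `scale(Xnew) %*% b + yCenter`.
#' @slot autoscale list with `means` and `sds` (column autoscaling parameters
#'   fitted on the calibration rows).
#' @slot yCenter mean of the calibration response.
#' @slot variables integer indices of the modelled variables within the
#'   full wavenumber grid the model was built from.
#' @slot wavenumbers wavenumbers (cm^-1) of the modelled variables.
#' @export
setClass("PLSModel",
  representation(
    nLv = "integer",
    weights = "matrix",
    loadings = "matrix",
    yLoadings = "numeric",
    scores = "matrix",
    regressionVector = "numeric",
    autoscale = "list",
    yCenter = "numeric",
    variables = "integer",
    wavenumbers = "numeric"
  )
)

setValidity("PLSModel", function(object) {
  msg <- character()
  k <- object@nLv
  if (length(k) != 1L || k < 1L) msg <- c(msg, "nLv must be a single count >= 1")
  if (ncol(object@weights) != k || ncol(object@loadings) != k ||
      ncol(object@scores) != k || length(object@yLoadings) != k) {
    msg <- c(msg, "latent-variable dimensions are inconsistent")
  }
  tt <- crossprod(object@scores)
  off <- tt - diag(diag(tt), nrow = nrow(tt))
  if (max(abs(off)) > 1e-8 * max(1, max(abs(diag(tt))))) {
    msg <- c(msg, "score columns are not mutually orthogonal")
  }
  if (length(msg)) msg else TRUE
})

#' IntervalSet: wavenumber windows used for interval PLS
#'
#' An ordered set of inclusive wavenumber windows together with the grid
#' column indices they resolve to (sorted, deduplicated).
#'
#' @slot ranges numeric matrix with columns `start` and `end` (cm^-1),
#'   one row per window, start < end.
#' @slot indices sorted, deduplicated integer column indices into the grid.
#' @slot wavenumbers the full grid the indices refer to.
#' @export
setClass("IntervalSet",
  representation(
    ranges = "matrix",
    indices = "integer",
    wavenumbers = "numeric"
  )
)

setValidity("IntervalSet", function(object) {
  msg <- character()
  r <- object@ranges
  if (nrow(r) < 1L) msg <- c(msg, "at least one interval is required")
  if (ncol(r) != 2L) msg <- c(msg, "ranges must have two columns (start, end)")
  if (nrow(r) >= 1L && ncol(r) == 2L && any(r[, 1L] >= r[, 2L])) {
    msg <- c(msg, "each interval must have start < end")
  }
  idx <- object@indices
  if (length(idx) == 0L) msg <- c(msg, "interval set resolves to no variables")
  if (is.unsorted(idx, strictly = TRUE)) {
    msg <- c(msg, "indices must be sorted and deduplicated")
  }
  if (length(idx) && (min(idx) < 1L || max(idx) > length(object@wavenumbers))) {
    msg <- c(msg, "indices outside the grid")
  }
  if (length(msg)) msg else TRUE
})

#' SplitResult: Kennard-Stone calibration/test partition
#'
#' @slot calibration character sample ids in selection order.
#' @slot test character sample ids not selected, in original row order.
#' @export
setClass("SplitResult",
  representation(calibration = "character", test = "character")
)

setValidity("SplitResult", function(object) {
  if (length(intersect(object@calibration, object@test))) {
    "calibration and test ids must be disjoint"
  } else TRUE
})

#' PermutationReport: Y-randomization test results
#'
#' @slot nPermutations number of response permutations.
#' @slot permutedR2cv cross-validated R2 of each permuted refit.
#' @slot realR2cv cross-validated R2 of the unpermuted model.
#' @slot pWilcoxon one-sided Wilcoxon signed-rank p-value on the paired
#'   differences real - permuted.
#' @slot pSign one-sided sign-test p-value on the same differences.
#' @slot pRandT empirical randomization p-value
#'   (1 + #\{permuted >= real\}) / (n + 1).
#' @slot passed named logical, each test at alpha = 0.05.
#' @export
setClass("PermutationReport",
  representation(
    nPermutations = "integer",
    permutedR2cv = "numeric",
    realR2cv = "numeric",
    pWilcoxon = "numeric",
    pSign = "numeric",
    pRandT = "numeric",
    passed = "logical"
  )
)

setValidity("PermutationReport", function(object) {
  msg <- character()
  if (length(object@permutedR2cv) != object@nPermutations) {
    msg <- c(msg, "permutedR2cv length must equal nPermutations")
  }
  p <- c(object@pWilcoxon, object@pSign, object@pRandT)
  if (any(p < 0 | p > 1)) msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ADReport: Williams-plot applicability-domain diagnostics
#'
#' @slot leverages per-sample leverage in latent-score space.
#' @slot warningLeverage h* = 3 (nLv + 1) / n_cal.
#' @slot studentizedResiduals per-sample studentized residuals (NA for query
#'   samples without a reference value).
#' @slot outsideDomain logical flags: leverage above h* or |residual| > 3.
#' @slot isCalibration logical, TRUE for calibration rows.
#' @export
setClass("ADReport",
  representation(
    leverages = "numeric",
    warningLeverage = "numeric",
    studentizedResiduals = "numeric",
    outsideDomain = "logical",
    isCalibration = "logical"
  )
)

setValidity("ADReport", function(object) {
  if (any(object@leverages < 0)) "leverages must be nonnegative" else TRUE
})

#' ValidationReport: calibration / cross-validation / prediction metrics
#'
#' @slot r2Cal,rmseCal calibration-set metrics.
#' @slot r2Cv,rmseCv leave-one-out cross-validation metrics.
#' @slot r2Pred,rmsePred external test-set metrics (NA when no test set).
#' @slot nLv latent variables of the reported model.
#' @slot permutation a [PermutationReport-class] or NULL.
#' @slot ad an [ADReport-class] or NULL.
#' @export
setClass("ValidationReport",
  representation(
    r2Cal = "numeric", rmseCal = "numeric",
    r2Cv = "numeric", rmseCv = "numeric",
    r2Pred = "numeric", rmsePred = "numeric",
    nLv = "integer",
    permutation = "ANY",
    ad = "ANY"
  ),
  prototype(permutation = NULL, ad = NULL)
)

setValidity("ValidationReport", function(object) {
  r <- c(object@rmseCal, object@rmseCv, object@rmsePred)
  if (any(r < 0, na.rm = TRUE)) "RMSE values must be nonnegative" else TRUE
})

#' CalibrationCurve: linear HPLC calibration with ICH Q2 LOD/LOQ
#'
#' @slot slope S, detector response per (ug/mL).
#' @slot intercept response at zero concentration.
#' @slot r2 determination coefficient of the fitted line.
#' @slot sigma standard deviation of the blank response (n >= 6).
#' @slot lod limit of detection, ng/mL (3.3 sigma / S).
#' @slot loq limit of quantification, ng/mL (10 sigma / S).
#' @slot rangeLow,rangeHigh calibrated concentration range, ug/mL.
#' @export
setClass("CalibrationCurve",
  representation(
    slope = "numeric", intercept = "numeric", r2 = "numeric",
    sigma = "numeric", lod = "numeric", loq = "numeric",
    rangeLow = "numeric", rangeHigh = "numeric"
  )
)

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (object@sigma > 0) {
    if (object@lod <= 0) msg <- c(msg, "lod must be positive when sigma > 0")
    if (abs(object@loq / object@lod - 10 / 3.3) > 1e-12) {
      msg <- c(msg, "loq/lod must equal 10/3.3")
    }
  }
  if (length(msg)) msg else TRUE
})

#' DoseResponseResult: DPPH dose-response summary
#'
#' @slot ec50 sample concentration scavenging 50\% of the radicals, in the
#'   units of the supplied concentrations.
#' @slot curve data.frame with columns `concentration` and `inhibition`
#'   (the monotone curve the EC50 was interpolated on).
#' @export
setClass("DoseResponseResult",
  representation(ec50 = "numeric", curve = "data.frame")
)

setValidity("DoseResponseResult", function(object) {
  cc <- object@curve$concentration
  if (length(cc) && (object@ec50 < min(cc) || object@ec50 > max(cc))) {
    "ec50 must lie within the measured concentration range"
  } else TRUE
})
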