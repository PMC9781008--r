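#' @include AllClasses.R
NULL

#' Accessors for spectra containers and fitted objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object an object of the documented class.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))

#' @rdname accessors
#' @export
setGeneric("absorbance", function(object) standardGeneric("absorbance"))

#' @rdname accessors
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))

#' @rdname accessors
#' @export
setGeneric("processing", function(object) standardGeneric("processing"))

#' @rdname accessors
#' @export
setGeneric("nSpectra", function(object) standardGeneric("nSpectra"))

#' @rdname accessors
#' @export
setGeneric("nLv", function(object) standardGeneric("nLv"))

#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("regressionVector", function(object) {
  standardGeneric("regressionVector")
})

#' @rdname accessors
#' @export
setGeneric("variableIndices", function(object) {
  standardGeneric("variableIndices")
})

#' @rdname accessors
#' @export
setGeneric("intervalRanges", function(object) standardGeneric("intervalRanges"))

#' @rdname accessors
#' @export
setGeneric("calibrationIds", function(object) {
  standardGeneric("calibrationIds")
})

#' @rdname accessors
#' @export
setGeneric("testIds", function(object) standardGeneric("testIds"))

#' @rdname accessors
#' @export
setGeneric("ec50", function(object) standardGeneric("ec50"))

#' @rdname accessors
#' @export
setGeneric("lod", function(object) standardGeneric("lod"))

#' @rdname accessors
#' @export
setGeneric("loq", function(object) standardGeneric("loq"))

#' @rdname accessors
#' @export
setMethod("wavenumbers", "SpectraSet", function(object) object@wavenumbers)

#' @rdname accessors
#' @export
setMethod("absorbance", "SpectraSet", function(object) object@absorbance)

#' @rdname accessors
#' @export
setMethod("sampleData", "SpectraSet", function(object) object@sampleData)

#' @rdname accessors
#' @export
setMethod("processing", "SpectraSet", function(object) object@processing)

#' @rdname accessors
#' @export
setMethod("nSpectra", "SpectraSet", function(object) nrow(object@absorbance))

#' @rdname accessors
#' @export
setMethod("nLv", "PLSModel", function(object) object@nLv)

#' @rdname accessors
#' @export
setMethod("nLv", "ValidationReport", function(object) object@nLv)

#' @rdname accessors
#' @export
setMethod("scores", "PLSModel", function(object) object@scores)

#' @rdname accessors
#' @export
setMethod("regressionVector", "PLSModel", function(object) {
  object@regressionVector
})

#' @rdname accessors
#' @export
setMethod("wavenumbers", "PLSModel", function(object) object@wavenumbers)

#' @rdname accessors
#' @export
setMethod("variableIndices", "PLSModel", function(object) object@variables)

#' @rdname accessors
#' @export
setMethod("variableIndices", "IntervalSet", function(object) object@indices)

#' @rdname accessors
#' @export
setMethod("intervalRanges", "IntervalSet", function(object) object@ranges)

#' @rdname accessors
#' @export
setMethod("wavenumbers", "IntervalSet", function(object) object@wavenumbers)

#' @rdname accessors
#' @export
setMethod("calibrationIds", "SplitResult", function(object) object@calibration)

#' @rdname accessors
#' @export
setMethod("testIds", "SplitResult", function(object) object@test)

#' @rdname accessors
#' @export
setMethod("ec50", "DoseResponseResult", function(object) object@ec50)

#' @rdname accessors
#' @export
setMethod("lod", "CalibrationCurve", function(object) object@lod)

#' @rdname accessors
#' @export
setMethod("loq", "CalibrationCurve", function(object) object@loq)

setMethod("show", "SpectraSet", function(object) {
  wn <- object@wavenumbers
  cat(sprintf(
    "SpectraSet: %d spectra x %d variables (%.1f-%.1f cm-1)\n",
    nrow(object@absorbance), length(wn), min(wn), max(wn)
  ))
  proc <- if (length(object@processing)) {
    paste(object@processing, collapse = " -> ")
  } else "none"
  cat("  processing:", proc, "\n")
  if ("product_id" %in% names(object@sampleData)) {
    cat("  products:", length(unique(object@sampleData$product_id)), "\n")
  }
  invisible(NULL)
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf(
    "PLSModel: %d latent variable(s), %d variables, %d calibration samples\n",
    object@nLv, length(object@variables), nrow(object@scores)
  ))
  invisible(NULL)
})

setMethod("show", "IntervalSet", function(object) {
  cat(sprintf(
    "IntervalSet: %d window(s), %d variables\n",
    nrow(object@ranges), length(object@indices)
  ))
  apply(object@ranges, 1L, function(r) {
    cat(sprintf("  %.1f-%.1f cm-1\n", r[1L], r[2L]))
  })
  invisible(NULL)
})

setMethod("show", "SplitResult", function(object) {
  cat(sprintf(
    "SplitResult: %d calibration, %d test\n",
    length(object@calibration), length(object@test)
  ))
  invisible(NULL)
})

setMethod("show", "PermutationReport", function(object) {
  cat(sprintf(
    "PermutationReport: real R2cv = %.4f over %d permutations\n",
    object@realR2cv, object@nPermutations
  ))
  cat(sprintf(
    "  p(Wilcoxon) = %.4g, p(sign) = %.4g, p(randomization) = %.4g\n",
    object@pWilcoxon, object@pSign, object@pRandT
  ))
  cat("  passed:", paste(names(object@passed)[object@passed], collapse = ", "),
      "\n")
  invisible(NULL)
})

setMethod("show", "ADReport", function(object) {
  cat(sprintf(
    "ADReport: %d samples, h* = %.4f, %d outside domain\n",
    length(object@leverages), object@warningLeverage,
    sum(object@outsideDomain, na.rm = TRUE)
  ))
  invisible(NULL)
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport (", object@nLv, "LV )\n")
  cat(sprintf("  CAL : R2 = %.4f, RMSE = %.4g\n", object@r2Cal, object@rmseCal))
  cat(sprintf("  CV  : R2 = %.4f, RMSE = %.4g\n", object@r2Cv, object@rmseCv))
  if (!is.na(object@r2Pred)) {
    cat(sprintf("  PRED: R2 = %.4f, RMSE = %.4g\n",
                object@r2Pred, object@rmsePred))
  } else {
    cat("  PRED: no test set\n")
  }
  invisible(NULL)
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve: y = %.4gx %+.4g (R2 = %.4f)\n",
    object@slope, object@intercept, object@r2
  ))
  cat(sprintf("  LOD = %.4g ng/mL, LOQ = %.4g ng/mL\n",
              object@lod, object@loq))
  invisible(NULL)
})

setMethod("show", "DoseResponseResult", function(object) {
  cat(sprintf("DoseResponseResult: EC50 = %.4g (%d curve points)\n",
              object@ec50, nrow(object@curve)))
  invisible(NULL)
})
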