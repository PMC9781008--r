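#' Linear HPLC calibration with ICH Q2 detection and quantification limits
#'
#' Fits an ordinary least-squares line through the calibration levels,
#' estimates sigma as the sample standard deviation of the blank responses
#' and reports `LOD = 3.3 sigma / S` and `LOQ = 10 sigma / S` (converted
#' from ug/mL to ng/mL; LOQ is computed from LOD so the 10/3.3 ratio is
#' exact).
#'
#' @param levels concentration levels, ug/mL (>= 3 distinct values).
#' @param areas detector responses, same length.
#' @param blanks blank responses, n >= 6.
#' @return a [CalibrationCurve-class].
#' @examples
#' lv <- rep(c(5, 10, 20, 40), each = 2)
#' fitCalibrationCurve(lv, 88.68 * lv - 0.06, blanks = rep(0.1, 6))
#' @export
fitCalibrationCurve <- function(levels, areas, blanks) {
  if (length(unique(levels)) < 3L) stop("need >= 3 distinct levels")
  if (length(levels) != length(areas)) stop("levels/areas length mismatch")
  if (length(blanks) < 6L) stop("need >= 6 blank responses")
  fit <- stats::lm(areas ~ levels)
  slope <- unname(stats::coef(fit)[2L])
  if (slope <= 0) stop("invalid calibration: nonpositive slope")
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((areas - mean(areas))^2)
  sigma <- stats::sd(blanks)
  lodNg <- 3.3 * sigma / slope * 1000  # ug/mL -> ng/mL
  methods::new("CalibrationCurve",
    slope = slope, intercept = intercept, r2 = r2, sigma = sigma,
    lod = lodNg, loq = lodNg * (10 / 3.3),
    rangeLow = min(levels), rangeHigh = max(levels)
  )
}

#' Quantification limit implied by a detection limit
#'
#' Under the ICH Q2 formulas LOD = 3.3 sigma/S and LOQ = 10 sigma/S, so
#' LOQ = LOD * 10 / 3.3 regardless of sigma and S.
#'
#' @param lod limit of detection (any concentration unit).
#' @return the limit of quantification in the same unit.
#' @export
loqFromLod <- function(lod) {
  if (any(lod < 0)) stop("lod must be nonnegative")
  lod * (10 / 3.3)
}

#' Spike-recovery percentage
#'
#' `100 * (foundSpiked - foundUnspiked) / added`. Values outside 50-120%
#' are flagged as suspect via the `"suspect"` attribute (the value is still
#' returned).
#'
#' @param foundSpiked amount found in the spiked material.
#' @param foundUnspiked amount found in the unspiked material.
#' @param added amount of standard added (> 0).
#' @return recovery percent with a logical `"suspect"` attribute.
#' @export
recoveryPercent <- function(foundSpiked, foundUnspiked, added) {
  if (any(added <= 0)) stop("added must be > 0")
  rec <- 100 * (foundSpiked - foundUnspiked) / added
  structure(rec, suspect = rec > 120 | rec < 50)
}

#' Relative standard deviation (%RSD) of replicate measurements
#'
#' @param values >= 2 replicate measurements with nonzero mean.
#' @return `100 * sd(values) / mean(values)` (sample sd, n-1).
#' @export
rsdPercent <- function(values) {
  if (length(values) < 2L) stop("need >= 2 replicate values")
  m <- mean(values)
  if (m == 0) stop("%RSD undefined for zero mean")
  100 * stats::sd(values) / m
}

#' DPPH radical-scavenging inhibition percentage
#'
#' `100 * (aBlank - aSample) / aBlank`, clipped to [0, 100]; when clipping
#' occurs the result carries a `"clipped"` attribute.
#'
#' @param aBlank blank absorbance at 517 nm (> 0).
#' @param aSample sample absorbance at 517 nm.
#' @return inhibition percent.
#' @export
dpphInhibition <- function(aBlank, aSample) {
  if (any(aBlank <= 0)) stop("blank absorbance must be > 0")
  raw <- 100 * (aBlank - aSample) / aBlank
  out <- pmin(100, pmax(0, raw))
  if (any(out != raw)) attr(out, "clipped") <- TRUE
  out
}

#' EC50 from a dose-response curve by bracketing interpolation
#'
#' The inhibition curve is first made monotone non-decreasing in
#' concentration by isotonic regression (pooled adjacent violators), then
#' the EC50 is linearly interpolated between the two points bracketing 50%
#' inhibition. A point exactly at 50% returns its concentration.
#'
#' @param concentration positive concentrations (>= 2 points).
#' @param inhibition percent inhibition at each concentration.
#' @return a [DoseResponseResult-class].
#' @examples
#' ec50(ec50FromCurve(c(1, 3), c(25, 75)))  # 2
#' @export
ec50FromCurve <- function(concentration, inhibition) {
  if (length(concentration) < 2L) stop("need >= 2 curve points")
  if (length(concentration) != length(inhibition)) stop("length mismatch")
  o <- order(concentration)
  conc <- concentration[o]
  iso <- stats::isoreg(conc, inhibition[o])$yf
  exact <- which(iso == 50)
  if (length(exact)) {
    ec <- conc[exact[1L]]
  } else {
    above <- which(iso > 50)
    below <- which(iso < 50)
    if (!length(above) || !length(below) || min(above) < max(below)) {
      stop("EC50 outside measured range")
    }
    i <- max(below); j <- min(above)
    ec <- conc[i] + (50 - iso[i]) * (conc[j] - conc[i]) / (iso[j] - iso[i])
  }
  methods::new("DoseResponseResult",
    ec50 = ec,
    curve = data.frame(concentration = conc, inhibition = iso)
  )
}

#' Convert extract concentration to content per gram of raw material
#'
#' `concentration * extractVolume / sampleMass`; with the standard workup
#' of ~500 mg material extracted into 15 mL, 10 ug/mL corresponds to
#' 300 ug/g.
#'
#' @param concExtract analyte concentration in the extract, ug/mL.
#' @param extractVolume extraction volume, mL (default 15).
#' @param sampleMass mass of raw material, g (default 0.5).
#' @return content in ug per g of raw material.
#' @export
contentPerGram <- function(concExtract, extractVolume = 15, sampleMass = 0.5) {
  if (any(extractVolume <= 0) || any(sampleMass <= 0)) {
    stop("volume and mass must be positive")
  }
  concExtract * extractVolume / sampleMass
}

#' Recommended-dietary-intake coverage of a supplement dose
#'
#' Percentage of the daily reference DNJ intake (default 30 mg) delivered
#' by the manufacturer-recommended daily dose:
#' `100 * (content * unitMass * unitsPerDay / 1000) / rdiMg`.
#'
#' @param dnjContent DNJ content in the raw material, ug/g.
#' @param unitMass raw material per tablet/capsule (or daily tea portion), g.
#' @param unitsPerDay units taken per day.
#' @param rdiMg recommended daily intake, mg (default 30).
#' @return coverage percent.
#' @export
rdiCoverage <- function(dnjContent, unitMass, unitsPerDay, rdiMg = 30) {
  if (any(rdiMg <= 0)) stop("rdiMg must be positive")
  if (any(unitMass <= 0) || any(unitsPerDay <= 0)) {
    stop("unitMass and unitsPerDay must be positive")
  }
  100 * (dnjContent * unitMass * unitsPerDay / 1000) / rdiMg
}

#' Method-validation summary table
#'
#' Collects per-analyte validation quantities into the conventional row
#' layout: range, regression equation, R2, recovery, %RSD, LOD, LOQ.
#'
#' @param curves named list of [CalibrationCurve-class] objects.
#' @param recovery named numeric vector of recovery percents (optional).
#' @param rsd named numeric vector of %RSD values (optional).
#' @return data.frame, one column per analyte.
#' @export
validationSummaryTable <- function(curves, recovery = NULL, rsd = NULL) {
  cols <- lapply(names(curves), function(nm) {
    cc <- curves[[nm]]
    c(
      range_ug_mL = sprintf("%.2f-%.2f", cc@rangeLow, cc@rangeHigh),
      equation = sprintf("y = %.2fx %+.2f", cc@slope, cc@intercept),
      r2 = sprintf("%.3f", cc@r2),
      recovery_pct = if (!is.null(recovery) && nm %in% names(recovery)) {
        sprintf("%.1f", recovery[[nm]])
      } else NA_character_,
      rsd_pct = if (!is.null(rsd) && nm %in% names(rsd)) {
        sprintf("%.1f", rsd[[nm]])
      } else NA_character_,
      lod_ng_mL = sprintf("%.2f", cc@lod),
      loq_ng_mL = sprintf("%.2f", cc@loq)
    )
  })
  out <- as.data.frame(cols, col.names = names(curves))
  out
}
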