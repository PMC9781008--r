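#' Describe one absorption band
#'
#' A single vibrational band with Gaussian or Lorentzian line shape. The
#' Gaussian profile is `h * exp(-ln 2 * ((v - c) / w)^2)` and the Lorentzian
#' `h * w^2 / ((v - c)^2 + w^2)`, so `w` is the half-width at half-maximum in
#' both cases and the profile equals `h / 2` at `c +/- w`.
#'
#' @param center band centre, cm^-1.
#' @param width half-width at half-maximum, cm^-1 (> 0).
#' @param height peak absorbance (a.u., >= 0).
#' @param shape "gaussian" or "lorentzian".
#' @return a `BandSpec` (named list).
#' @export
bandSpec <- function(center, width, height, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (width <= 0) stop("band width must be > 0")
  if (height < 0) stop("band height must be >= 0")
  structure(
    list(center = center, width = width, height = height, shape = shape),
    class = "BandSpec"
  )
}

#' Describe a chemical component as a set of bands
#'
#' @param name component label, e.g. "DNJ".
#' @param bands list of [bandSpec()] objects (at least one).
#' @param concRange optional two-element concentration range the component is
#'   drawn from per product; the analyte component defaults to the range of
#'   the simulation config, any other component must provide one.
#' @return a `ComponentSpec` (named list).
#' @export
componentSpec <- function(name, bands, concRange = NULL) {
  if (length(bands) < 1L) stop("a component needs at least one band")
  if (!all(vapply(bands, inherits, logical(1L), "BandSpec"))) {
    stop("bands must be a list of bandSpec() objects")
  }
  if (!is.null(concRange) && (length(concRange) != 2L ||
      concRange[1L] > concRange[2L])) {
    stop("concRange must be c(low, high) with low <= high")
  }
  structure(
    list(name = name, bands = bands, concRange = concRange),
    class = "ComponentSpec"
  )
}

#' Simulation settings for the synthetic spectra generator
#'
#' Defaults emulate the measurement design the package targets: 19 herbal
#' products measured in triplicate over 750-4000 cm^-1. The grid spacing
#' default of 3.2 cm^-1 makes a ~95 cm^-1 window resolve to ~30 variables,
#' consistent with an interval size of 30 grid points.
#'
#' @param gridStart,gridEnd wavenumber range, cm^-1.
#' @param gridSpacing grid point spacing, cm^-1.
#' @param nProducts number of products (distinct true concentrations).
#' @param replicatesPerProduct replicate spectra per product (>= 1).
#' @param concLow,concHigh analyte concentration range, ug/g; per-product true
#'   values are drawn uniformly from it.
#' @param noiseSd additive white-noise standard deviation, absorbance units.
#' @param baselinePolyOrder order of the random polynomial baseline drift.
#' @param baselineAmplitude scale of the random baseline coefficients (a.u.).
#' @param scatterSd spread of the per-replicate multiplicative scatter factor
#'   `1 + Normal(0, scatterSd)`.
#' @param seed RNG seed; identical configs and seeds give bit-identical data.
#' @return a `SimulationConfig` (named list).
#' @export
simulationConfig <- function(gridStart = 750, gridEnd = 4000,
                             gridSpacing = 3.2, nProducts = 19L,
                             replicatesPerProduct = 3L,
                             concLow = 0, concHigh = 1000,
                             noiseSd = 0.002, baselinePolyOrder = 2L,
                             baselineAmplitude = 0.05, scatterSd = 0.05,
                             seed = 1L) {
  if (gridStart >= gridEnd) stop("gridStart must be < gridEnd")
  if (gridSpacing <= 0) stop("gridSpacing must be > 0")
  if (concLow >= concHigh) stop("concLow must be < concHigh")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (replicatesPerProduct < 1L) stop("replicatesPerProduct must be >= 1")
  if (nProducts < 1L) stop("nProducts must be >= 1")
  structure(
    list(
      gridStart = gridStart, gridEnd = gridEnd, gridSpacing = gridSpacing,
      nProducts = as.integer(nProducts),
      replicatesPerProduct = as.integer(replicatesPerProduct),
      concLow = concLow, concHigh = concHigh, noiseSd = noiseSd,
      baselinePolyOrder = as.integer(baselinePolyOrder),
      baselineAmplitude = baselineAmplitude, scatterSd = scatterSd,
      seed = as.integer(seed)
    ),
    class = "SimulationConfig"
  )
}

#' Default component set: DNJ analyte in a plant-matrix background
#'
#' The analyte carries pyranose-ring C-O/C-C stretching and N-H / C-H bending
#' character with bands centred at 1150, 1380 and 1650 cm^-1, inside the
#' three diagnostic windows (1101-1196, 1333-1427, 1603-1697 cm^-1). Band
#' heights are expressed per ug/g so a 1000 ug/g sample peaks near 1 a.u.
#' The "matrix" component mimics the carbohydrate/protein/O-H background of
#' dried leaf material with bands at 1047, 1205, 1541, 1745, 2920 and
#' 3300 cm^-1 and a bulk level fluctuating around 1.
#'
#' @return list of two [componentSpec()] objects named "DNJ" and "matrix".
#' @export
defaultComponents <- function() {
  list(
    componentSpec("DNJ", list(
      bandSpec(1150, 20, 1.0e-3),
      bandSpec(1380, 18, 0.8e-3),
      bandSpec(1650, 15, 0.6e-3)
    )),
    componentSpec("matrix", list(
      bandSpec(1047, 30, 0.40),
      bandSpec(1205, 25, 0.20),
      bandSpec(1541, 20, 0.30),
      bandSpec(1745, 25, 0.15),
      bandSpec(2920, 40, 0.35, "lorentzian"),
      bandSpec(3300, 150, 0.50)
    ), concRange = c(0.8, 1.2))
  )
}

#' Evaluate a pure-component spectrum on a wavenumber grid
#'
#' Band contributions sum; the result is a nonnegative absorbance vector.
#'
#' @param component a [componentSpec()].
#' @param grid strictly monotone wavenumber vector (cm^-1).
#' @return numeric absorbance vector, one value per grid point.
#' @examples
#' g <- seq(1000, 1300, by = 4)
#' renderComponent(componentSpec("x", list(bandSpec(1150, 20, 1))), g)
#' @export
renderComponent <- function(component, grid) {
  if (length(grid) == 0L) stop("empty wavenumber grid")
  d <- diff(grid)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("grid must be strictly monotone")
  }
  lo <- min(grid); hi <- max(grid)
  out <- numeric(length(grid))
  for (b in component$bands) {
    if (b$center < lo || b$center > hi) {
      stop(sprintf(
        "band at %.1f cm-1 (component '%s') lies outside the grid [%g, %g]",
        b$center, component$name, lo, hi
      ))
    }
    out <- out + switch(b$shape,
      gaussian = b$height * exp(-log(2) * ((grid - b$center) / b$width)^2),
      lorentzian = b$height * b$width^2 / ((grid - b$center)^2 + b$width^2)
    )
  }
  out
}

#' Generate a synthetic spectra dataset
#'
#' Builds a Beer-Lambert mixture: each product draws one concentration per
#' component (uniform over that component's range), and each replicate
#' spectrum is `scatter * (conc %*% pure spectra) + baseline + noise` with a
#' per-replicate multiplicative scatter factor, a random polynomial baseline
#' and additive white noise. The analyte's true concentration is recorded in
#' the sample metadata as the regression response.
#'
#' @param cfg a [simulationConfig()].
#' @param components list of [componentSpec()]; the analyte is identified by
#'   name and uses the config concentration range unless it carries its own.
#' @param analyte name of the analyte component.
#' @return a [SpectraSet-class] with columns `sample_id`, `product_id`,
#'   `replicate`, `concentration`, `role` in its metadata.
#' @examples
#' cfg <- simulationConfig(nProducts = 4, seed = 7)
#' ds <- generateDataset(cfg)
#' nSpectra(ds)  # 4 products x 3 replicates = 12
#' @export
generateDataset <- function(cfg, components = defaultComponents(),
                            analyte = "DNJ") {
  if (length(components) == 0L) stop("at least one component is required")
  nms <- vapply(components, `[[`, character(1L), "name")
  if (!analyte %in% nms) {
    stop(sprintf("analyte component '%s' not found", analyte))
  }
  grid <- seq(cfg$gridStart, cfg$gridEnd, by = cfg$gridSpacing)
  pure <- t(vapply(components, renderComponent, numeric(length(grid)),
                   grid = grid))
  nP <- cfg$nProducts
  nR <- cfg$replicatesPerProduct
  withSeed(cfg$seed, {
    conc <- matrix(NA_real_, nrow = nP, ncol = length(components))
    for (j in seq_along(components)) {
      rng <- components[[j]]$concRange
      if (is.null(rng)) {
        if (nms[j] != analyte) {
          stop(sprintf("component '%s' needs a concRange", nms[j]))
        }
        rng <- c(cfg$concLow, cfg$concHigh)
      }
      conc[, j] <- stats::runif(nP, rng[1L], rng[2L])
    }
    mixture <- conc %*% pure
    tnorm <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
    basis <- outer(tnorm, 0:cfg$baselinePolyOrder, `^`)
    n <- nP * nR
    X <- matrix(NA_real_, nrow = n, ncol = length(grid))
    row <- 0L
    for (i in seq_len(nP)) {
      for (r in seq_len(nR)) {
        row <- row + 1L
        scatter <- 1 + stats::rnorm(1L, 0, cfg$scatterSd)
        coefs <- stats::runif(cfg$baselinePolyOrder + 1L, -1, 1) *
          cfg$baselineAmplitude
        X[row, ] <- scatter * mixture[i, ] +
          drop(basis %*% coefs) +
          stats::rnorm(length(grid), 0, cfg$noiseSd)
      }
    }
  })
  productId <- sprintf("P%02d", rep(seq_len(nP), each = nR))
  replicate <- rep(seq_len(nR), times = nP)
  meta <- data.frame(
    sample_id = sprintf("%s_r%d", productId, replicate),
    product_id = productId,
    replicate = replicate,
    concentration = rep(conc[, match(analyte, nms)], each = nR),
    role = NA_character_,
    stringsAsFactors = FALSE
  )
  spectraSet(grid, X, meta)
}

#' Simulate an HPLC linear-calibration table
#'
#' Peak areas follow `area = slope * conc + intercept + Normal(0, sigmaBlank)`
#' at each level and replicate; six blank injections (concentration 0) are
#' appended for the blank-response standard deviation used by the ICH Q2
#' LOD/LOQ formulas. The default line is the DNJ preset
#' `y = 88.68 x - 0.06`.
#'
#' @param slope detector response per (ug/mL).
#' @param intercept response at zero concentration.
#' @param sigmaBlank response noise standard deviation (>= 0).
#' @param levels concentration levels, ug/mL (non-empty).
#' @param replicates injections per level (>= 1).
#' @param nBlanks blank injections appended (default 6).
#' @param seed RNG seed.
#' @return data.frame with columns `concentration`, `area`, `replicate`,
#'   `is_blank`.
#' @export
generateHplcCalibration <- function(slope = 88.68, intercept = -0.06,
                                    sigmaBlank = 0.5,
                                    levels = c(3.14, 10, 25, 50, 100, 157.14),
                                    replicates = 3L, nBlanks = 6L, seed = 1L) {
  if (length(levels) == 0L) stop("levels must be non-empty")
  if (replicates < 1L) stop("replicates must be >= 1")
  if (sigmaBlank < 0) stop("sigmaBlank must be >= 0")
  conc <- c(rep(levels, each = replicates), rep(0, nBlanks))
  rep_id <- c(rep(seq_len(replicates), times = length(levels)),
              seq_len(nBlanks))
  withSeed(seed, {
    area <- slope * conc + intercept + stats::rnorm(length(conc), 0, sigmaBlank)
  })
  data.frame(
    concentration = conc, area = area, replicate = rep_id,
    is_blank = conc == 0, stringsAsFactors = FALSE
  )
}

#' Simulate a DPPH dose-response table
#'
#' Inhibition follows the logistic `100 / (1 + (ec50/c)^hill)` plus additive
#' noise, clipped to [0, 100].
#'
#' @param ec50True true half-maximal concentration (> 0).
#' @param hill Hill slope.
#' @param concGrid positive, sorted concentrations.
#' @param noiseSd noise standard deviation in percent inhibition.
#' @param seed RNG seed.
#' @return data.frame with columns `concentration`, `inhibition`.
#' @export
generateDoseResponse <- function(ec50True, hill = 1,
                                 concGrid = ec50True * 2^seq(-3, 4),
                                 noiseSd = 0, seed = 1L) {
  if (ec50True <= 0) stop("ec50True must be > 0")
  if (any(concGrid <= 0)) stop("concentrations must be positive")
  if (is.unsorted(concGrid)) stop("concGrid must be sorted increasing")
  inhib <- 100 / (1 + (ec50True / concGrid)^hill)
  withSeed(seed, {
    inhib <- inhib + stats::rnorm(length(concGrid), 0, noiseSd)
  })
  data.frame(
    concentration = concGrid,
    inhibition = pmin(100, pmax(0, inhib))
  )
}
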