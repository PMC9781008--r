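#' Write a SpectraSet as delimited text
#'
#' The spectra file has the wavenumber as its first column and one column
#' per spectrum, with sample ids in the header; values are written in full
#' double precision so a read-back is lossless. The sample metadata table is
#' written alongside when a path is given.
#'
#' @param ss a [SpectraSet-class].
#' @param path spectra file path.
#' @param metadataPath optional metadata table path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(ss, path, metadataPath = NULL, sep = ",") {
  X <- absorbance(ss)
  # apply over rows yields a variables x samples block of formatted values
  cols <- apply(X, 1L, function(r) format(r, digits = 17, trim = TRUE))
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = 1L)
  df <- data.frame(
    wavenumber = format(wavenumbers(ss), digits = 17, trim = TRUE),
    cols, check.names = FALSE, stringsAsFactors = FALSE
  )
  names(df) <- c("wavenumber", sampleData(ss)$sample_id)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(metadataPath)) {
    utils::write.table(sampleData(ss), metadataPath, sep = sep,
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read spectra from delimited text or JCAMP-DX
#'
#' The delimited dialect expects a header row of sample ids, the wavenumber
#' in the first column and one absorbance column per spectrum. A descending
#' wavenumber grid is accepted and reversed to ascending (with a message);
#' ragged rows, non-numeric cells and duplicate sample ids are errors that
#' name the offending location. The JCAMP-DX dialect reads a single-spectrum
#' `##XYDATA=(X++(Y..Y))` block in AFFN form onto the same internal
#' representation.
#'
#' @param path spectra file.
#' @param dialect "delimited" or "jcamp".
#' @param metadataPath optional metadata table (delimited dialect only).
#' @param sep field separator for the delimited dialect.
#' @return a [SpectraSet-class].
#' @export
readSpectra <- function(path, dialect = c("delimited", "jcamp"),
                        metadataPath = NULL, sep = ",") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("spectra file not found: ", path)
  if (dialect == "jcamp") return(readSpectraJcamp(path))
  lines <- readLines(path)
  header <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  ids <- header[-1L]
  if (anyDuplicated(ids)) {
    stop("duplicate sample id '", ids[duplicated(ids)][1L], "' in header")
  }
  body <- strsplit(lines[-1L], sep, fixed = TRUE)
  nc <- lengths(body)
  if (any(nc != length(header))) {
    stop("ragged row at line ", which(nc != length(header))[1L] + 1L)
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(body)), ncol = length(header), byrow = TRUE)
  )
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at line %d, column %d",
                 bad[1L] + 1L, bad[2L]))
  }
  wn <- vals[, 1L]
  X <- t(vals[, -1L, drop = FALSE])
  if (length(wn) > 1L && all(diff(wn) < 0)) {
    message("descending wavenumber grid reversed to ascending")
    wn <- rev(wn)
    X <- X[, rev(seq_len(ncol(X))), drop = FALSE]
  }
  meta <- if (!is.null(metadataPath)) {
    utils::read.table(metadataPath, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = ids, stringsAsFactors = FALSE)
  }
  rownames(X) <- ids
  spectraSet(wn, X, meta)
}

# Minimal JCAMP-DX reader: one spectrum, ##XYDATA=(X++(Y..Y)), AFFN values.
readSpectraJcamp <- function(path) {
  lines <- readLines(path)
  getLabel <- function(label) {
    hit <- grep(paste0("^##", label, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^##", label, "="), "", hit[1L])
  }
  title <- getLabel("TITLE")
  xFactor <- as.numeric(getLabel("XFACTOR"))
  yFactor <- as.numeric(getLabel("YFACTOR"))
  if (is.na(xFactor)) xFactor <- 1
  if (is.na(yFactor)) yFactor <- 1
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("no ##XYDATA block in ", path)
  end <- grep("^##END=", lines)
  end <- if (length(end)) min(end[end > start[1L]]) else length(lines) + 1L
  rows <- lines[(start[1L] + 1L):(end - 1L)]
  wn <- numeric(); ab <- list()
  for (r in rows) {
    vals <- as.numeric(strsplit(trimws(r), "[ \t]+")[[1L]])
    if (anyNA(vals) || length(vals) < 2L) {
      stop("unparseable JCAMP data line: ", r)
    }
    # per-line X is the first abscissa; spacing comes from consecutive lines
    wn <- c(wn, vals[1L] * xFactor)
    ab[[length(ab) + 1L]] <- vals[-1L] * yFactor
  }
  counts <- lengths(ab)
  dx <- if (length(wn) > 1L) (wn[2L] - wn[1L]) / counts[1L] else 1
  grid <- unlist(lapply(seq_along(wn), function(i) {
    wn[i] + dx * (seq_len(counts[i]) - 1L)
  }))
  y <- unlist(ab)
  if (grid[1L] > grid[length(grid)]) {
    grid <- rev(grid); y <- rev(y)
  }
  id <- if (is.na(title) || !nzchar(title)) "jcamp" else title
  spectraSet(grid, matrix(y, nrow = 1L, dimnames = list(id, NULL)),
             data.frame(sample_id = id, stringsAsFactors = FALSE))
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis. The defaults mirror
#' the reference workflow: a 15:19 calibration share, interval size 30,
#' step 10, "auto" stopping, 6 latent variables and 100 response
#' permutations.
#'
#' @param simulation a [simulationConfig()] used when no spectra path is
#'   given.
#' @param spectraPath,metadataPath optional delimited input files.
#' @param outputDir directory for artifacts (created if missing).
#' @param calFraction calibration share of the products (default 15/19).
#' @param intervalSize,step iPLS window settings (variables).
#' @param presetIntervals optional list of `c(start, end)` cm^-1 ranges to
#'   use instead of the forward search (e.g. [dnjIntervalPreset()]).
#' @param nLv latent variables (NA = choose by [selectNLv()]).
#' @param nPermutations Y-randomization permutations (0 disables the test).
#' @param polyOrder baseline polynomial order.
#' @param seed RNG seed recorded in every artifact.
#' @return a `RunConfig` (named list).
#' @export
runConfig <- function(simulation = simulationConfig(),
                      spectraPath = NULL, metadataPath = NULL,
                      outputDir = tempfile("dnjftir_run_"),
                      calFraction = 15 / 19,
                      intervalSize = 30L, step = 10L,
                      presetIntervals = NULL,
                      nLv = 6L, nPermutations = 100L,
                      polyOrder = 2L, seed = 1L) {
  structure(
    list(
      simulation = simulation, spectraPath = spectraPath,
      metadataPath = metadataPath, outputDir = outputDir,
      calFraction = calFraction, intervalSize = as.integer(intervalSize),
      step = as.integer(step), presetIntervals = presetIntervals,
      nLv = nLv, nPermutations = as.integer(nPermutations),
      polyOrder = as.integer(polyOrder), seed = as.integer(seed)
    ),
    class = "RunConfig"
  )
}

configHash <- function(cfg) {
  textHash(paste(deparse(cfg[setdiff(names(cfg), "outputDir")]),
                 collapse = ""))
}

#' Run the full calibration pipeline
#'
#' Chains every stage: simulate (or load) spectra, preprocess (replicate
#' averaging, baseline, SNV), Kennard-Stone split, interval selection
#' (forward iPLS or a preset), PLS fit, validation (calibration / LOO-CV /
#' external metrics, Y-randomization, applicability domain) and artifact
#' writing. Every artifact file starts with a comment line recording the
#' seed and a hash of the configuration; a stage log records parameters and
#' metric outcomes. Any stage error aborts with the stage name; artifacts
#' already written are retained.
#'
#' @param cfg a [runConfig()].
#' @return list with `report` (a [ValidationReport-class]), `model`,
#'   `intervals`, `split`, `dataset` (preprocessed) and `log` (data.frame).
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (!is.null(cfg$spectraPath) && !file.exists(cfg$spectraPath)) {
    stop("stage input: spectra path not found: ", cfg$spectraPath)
  }
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(cfg)
  stamp <- sprintf("# seed: %d  config: %s", cfg$seed, hash)
  logRows <- list()
  note <- function(stage, ...) {
    logRows[[length(logRows) + 1L]] <<- data.frame(
      stage = stage, detail = sprintf(...), stringsAsFactors = FALSE
    )
  }
  withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ds <- withStage("input", {
    if (!is.null(cfg$spectraPath)) {
      readSpectra(cfg$spectraPath, metadataPath = cfg$metadataPath)
    } else {
      sim <- cfg$simulation
      sim$seed <- cfg$seed
      generateDataset(sim)
    }
  })
  note("input", "%d spectra x %d variables", nSpectra(ds),
       length(wavenumbers(ds)))

  prep <- withStage("preprocess", {
    preprocessPipeline(ds, polyOrder = cfg$polyOrder)
  })
  note("preprocess", "chain: %s; %d product spectra",
       paste(processing(prep), collapse = " -> "), nSpectra(prep))

  split <- withStage("split", {
    kennardStone(prep, nCal = max(2L, round(nSpectra(prep) * cfg$calFraction)))
  })
  note("split", "%d calibration / %d test", length(calibrationIds(split)),
       length(testIds(split)))
  writeSplit(split, file.path(cfg$outputDir, "split.tsv"))

  calSet <- subsetSamples(prep, calibrationIds(split))
  testSet <- subsetSamples(prep, testIds(split))
  yCal <- sampleData(calSet)$concentration
  yTest <- sampleData(testSet)$concentration
  wn <- wavenumbers(prep)

  sel <- withStage("intervals", {
    if (!is.null(cfg$presetIntervals)) {
      iv <- resolveIntervals(wn, cfg$presetIntervals)
      list(intervals = iv, history = NULL)
    } else {
      cand <- makeIntervals(wn, cfg$intervalSize, cfg$step)
      forwardIpls(absorbance(calSet), yCal, cand,
                  nLv = if (is.na(cfg$nLv)) 6L else cfg$nLv, grid = wn)
    }
  })
  intervals <- sel$intervals
  note("intervals", "%d window(s), %d variables",
       nrow(intervalRanges(intervals)), length(variableIndices(intervals)))
  writeIntervalSet(intervals, file.path(cfg$outputDir, "intervals.tsv"))
  if (!is.null(sel$history)) {
    utils::write.table(sel$history,
                       file.path(cfg$outputDir, "ipls_history.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  idx <- variableIndices(intervals)
  XcalI <- absorbance(calSet)[, idx, drop = FALSE]
  XtestI <- absorbance(testSet)[, idx, drop = FALSE]

  k <- withStage("latent-variables", {
    if (is.na(cfg$nLv)) {
      selectNLv(XcalI, yCal)$nLv
    } else {
      min(cfg$nLv, nrow(XcalI) - 2L, ncol(XcalI))
    }
  })
  note("latent-variables", "nLv = %d", k)

  ev <- withStage("validate", {
    evaluateModel(XcalI, yCal,
                  if (nrow(XtestI)) XtestI else NULL,
                  if (nrow(XtestI)) yTest else NULL, nLv = k)
  })
  model <- fitPls(XcalI, yCal, k, variables = idx, wavenumbers = wn[idx])
  report <- ev$report
  note("validate", "R2cal %.4f R2cv %.4f R2pred %.4f",
       report@r2Cal, report@r2Cv, report@r2Pred)

  if (cfg$nPermutations > 0L) {
    report@permutation <- withStage("y-randomization", {
      yRandomization(XcalI, yCal, cfg$nPermutations, k, seed = cfg$seed)
    })
    note("y-randomization", "p = %.4g / %.4g / %.4g",
         report@permutation@pWilcoxon, report@permutation@pSign,
         report@permutation@pRandT)
  }

  report@ad <- withStage("applicability-domain", {
    applicabilityDomain(model, XcalI, yCal,
                        if (nrow(XtestI)) XtestI else NULL,
                        if (nrow(XtestI)) yTest else NULL)
  })
  note("applicability-domain", "%d sample(s) outside domain",
       sum(report@ad@outsideDomain, na.rm = TRUE))

  withStage("artifacts", {
    writePlsModel(model, file.path(cfg$outputDir, "model.txt"))
    rp <- file.path(cfg$outputDir, "report.txt")
    writeValidationReport(report, rp)
    body <- readLines(rp)
    writeLines(c(stamp, body), rp)
    plotWilliams(report@ad, file.path(cfg$outputDir, "williams.png"))
    ad <- report@ad
    utils::write.table(
      data.frame(
        leverage = ad@leverages,
        studentized_residual = ad@studentizedResiduals,
        outside_domain = ad@outsideDomain,
        is_calibration = ad@isCalibration
      ),
      file.path(cfg$outputDir, "ad_table.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    log <- do.call(rbind, logRows)
    utils::write.table(log, file.path(cfg$outputDir, "run_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(
      c(stamp, utils::capture.output(utils::str(cfg, give.attr = FALSE))),
      file.path(cfg$outputDir, "config.txt")
    )
  })

  list(report = report, model = model, intervals = intervals, split = split,
       dataset = prep, log = do.call(rbind, logRows))
}
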