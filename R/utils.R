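# Internal helpers shared across modules.

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Stable polynomial rolling hash of a character scalar, as 8 hex digits.
# Used to stamp output artifacts with the configuration that produced them.
textHash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

sampleSd <- function(x) stats::sd(x)  # n-1 denominator, named for clarity

#' Construct a SpectraSet
#'
#' @param wavenumbers strictly increasing numeric grid (cm^-1).
#' @param absorbance numeric matrix, one row per spectrum.
#' @param sampleData data.frame with a unique `sample_id` column, one row per
#'   spectrum. If missing, ids `s1, s2, ...` are generated.
#' @param processing character vector of preprocessing stages already applied.
#' @return a [SpectraSet-class].
#' @examples
#' ss <- spectraSet(c(1000, 1004, 1008), matrix(rnorm(6), nrow = 2))
#' nSpectra(ss)
#' @export
spectraSet <- function(wavenumbers, absorbance, sampleData = NULL,
                       processing = character()) {
  absorbance <- as.matrix(absorbance)
  if (is.null(sampleData)) {
    sampleData <- data.frame(
      sample_id = paste0("s", seq_len(nrow(absorbance))),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(rownames(absorbance))) {
    rownames(absorbance) <- sampleData$sample_id
  }
  methods::new("SpectraSet",
    wavenumbers = as.numeric(wavenumbers),
    absorbance = absorbance,
    sampleData = sampleData,
    processing = processing
  )
}

# Look up absorbance rows by sample id, preserving the requested order.
spectraRows <- function(ss, ids) {
  pos <- match(ids, ss@sampleData$sample_id)
  if (anyNA(pos)) {
    stop("unknown sample id(s): ", paste(ids[is.na(pos)], collapse = ", "))
  }
  pos
}

#' Subset a SpectraSet by sample ids
#'
#' @param ss a [SpectraSet-class].
#' @param ids sample ids to keep, in the requested order.
#' @return a [SpectraSet-class] with the selected spectra.
#' @export
subsetSamples <- function(ss, ids) {
  pos <- spectraRows(ss, ids)
  spectraSet(ss@wavenumbers, ss@absorbance[pos, , drop = FALSE],
             ss@sampleData[pos, , drop = FALSE], ss@processing)
}
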