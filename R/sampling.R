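#' Kennard-Stone calibration/test split
#'
#' Deterministic max-min selection on Euclidean row distances: the first two
#' calibration samples are the most distant pair; each subsequent sample
#' maximizes its minimum distance to those already selected. Ties are broken
#' by the lowest row index, so the selection is fully reproducible. The
#' response is never consulted.
#'
#' @param X numeric matrix of (preprocessed) spectra, samples in rows, or a
#'   [SpectraSet-class].
#' @param nCal number of calibration samples, 2 <= nCal <= nrow(X). The
#'   default reproduces a 15:19 calibration share (15 of 19 products).
#' @return a [SplitResult-class]; calibration ids are in selection order.
#' @examples
#' X <- matrix(c(0, 1, 10), ncol = 1)
#' calibrationIds(kennardStone(X, 2))  # rows 1 and 3
#' @export
kennardStone <- function(X, nCal = NULL) {
  if (methods::is(X, "SpectraSet")) {
    ids <- sampleData(X)$sample_id
    X <- absorbance(X)
  } else {
    X <- as.matrix(X)
    ids <- rownames(X)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  }
  n <- nrow(X)
  if (is.null(nCal)) nCal <- max(2L, round(n * 15 / 19))
  if (nCal < 2L || nCal > n) stop("nCal must satisfy 2 <= nCal <= nrow(X)")
  D <- as.matrix(stats::dist(X))
  # seed pair: maximum pairwise distance, first (i < j) pair in row order
  best <- -Inf; pair <- c(1L, 2L)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (D[i, j] > best) {
        best <- D[i, j]
        pair <- c(i, j)
      }
    }
  }
  selected <- pair
  remaining <- setdiff(seq_len(n), selected)
  while (length(selected) < nCal) {
    minDist <- vapply(remaining, function(r) min(D[r, selected]),
                      numeric(1L))
    pick <- remaining[which.max(minDist)]  # which.max -> lowest index on ties
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  methods::new("SplitResult",
    calibration = ids[selected],
    test = ids[sort(remaining)]
  )
}

#' Write / read a split as a two-column text table
#'
#' @param split a [SplitResult-class].
#' @param path file path.
#' @return `writeSplit` returns `path` invisibly; `readSplit` the
#'   [SplitResult-class].
#' @export
writeSplit <- function(split, path) {
  df <- data.frame(
    sample_id = c(calibrationIds(split), testIds(split)),
    role = c(rep("calibration", length(calibrationIds(split))),
             rep("test", length(testIds(split)))),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSplit
#' @export
readSplit <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  methods::new("SplitResult",
    calibration = df$sample_id[df$role == "calibration"],
    test = df$sample_id[df$role == "test"]
  )
}
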