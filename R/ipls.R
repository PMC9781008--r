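#' Enumerate candidate interval windows over the variable grid
#'
#' Windows contain `intervalSize` consecutive variables and start every
#' `step` variables; a final window is anchored at the grid end so every
#' variable is covered by at least one window.
#'
#' @param grid wavenumber vector.
#' @param intervalSize window width in variables (>= 2); when it exceeds the
#'   grid length a single full-range window is returned.
#' @param step start-to-start stride in variables (>= 1).
#' @return list of integer index vectors, one per window.
#' @examples
#' length(makeIntervals(seq_len(100), 30, 10))  # 8 windows
#' @export
makeIntervals <- function(grid, intervalSize = 30L, step = 10L) {
  n <- length(grid)
  if (intervalSize < 2L) stop("intervalSize must be >= 2")
  if (step < 1L) stop("step must be >= 1")
  if (intervalSize >= n) return(list(seq_len(n)))
  starts <- seq(1L, n - intervalSize + 1L, by = step)
  if (starts[length(starts)] != n - intervalSize + 1L) {
    starts <- c(starts, n - intervalSize + 1L)
  }
  lapply(starts, function(s) seq(s, s + intervalSize - 1L))
}

#' Resolve named wavenumber ranges to an IntervalSet
#'
#' Returns all grid indices whose wavenumber lies in any of the inclusive
#' ranges. Touching or overlapping ranges merge into deduplicated indices.
#'
#' @param grid wavenumber vector.
#' @param ranges list of two-element `c(start, end)` ranges in cm^-1.
#' @return an [IntervalSet-class].
#' @export
resolveIntervals <- function(grid, ranges) {
  if (length(ranges) == 0L) stop("no ranges supplied")
  mat <- do.call(rbind, lapply(ranges, function(r) {
    if (length(r) != 2L || r[1L] >= r[2L]) {
      stop("each range must be c(start, end) with start < end")
    }
    as.numeric(r)
  }))
  colnames(mat) <- c("start", "end")
  idx <- sort(unique(unlist(lapply(seq_len(nrow(mat)), function(i) {
    which(grid >= mat[i, 1L] & grid <= mat[i, 2L])
  }))))
  if (length(idx) == 0L) {
    stop("ranges resolve to no grid points (outside the grid?)")
  }
  methods::new("IntervalSet",
    ranges = mat, indices = as.integer(idx), wavenumbers = as.numeric(grid)
  )
}

#' The three diagnostic DNJ windows
#'
#' The wavenumber windows 1101-1196, 1333-1427 and 1603-1697 cm^-1 from the
#' fingerprint region, covering pyranose-ring C-O/C-C stretching, C-H/O-C-H
#' bending and amine N-H vibrations characteristic of DNJ in leaf material.
#' Shipped as a preset so the final reported model can be rebuilt without
#' re-running the interval search.
#'
#' @return list of three `c(start, end)` ranges in cm^-1.
#' @export
dnjIntervalPreset <- function() {
  list(c(1101, 1196), c(1333, 1427), c(1603, 1697))
}

#' Stepwise-forward interval PLS variable selection
#'
#' Greedy forward search over candidate windows: at each round, every unused
#' window is provisionally added to the current selection, the PLS chain
#' (autoscaling refitted on the candidate variable subset) is cross-validated
#' by leave-one-out, and the window minimizing RMSE_CV is accepted. Under the
#' "auto" stop rule the search ends when the best addition improves RMSE_CV
#' by 0.5% (relative) or less; a hard cap on the number of windows can be
#' set instead.
#'
#' @param X preprocessed (baseline + SNV) matrix, samples x variables.
#' @param y reference concentrations.
#' @param candidates list of window index vectors from [makeIntervals()].
#' @param maxIntervals hard cap on accepted windows (default `Inf` = "auto",
#'   relative-improvement stopping only).
#' @param nLv latent-variable budget per evaluation; each fit is capped at
#'   `min(nLv, n - 2, #variables)` so small selections stay feasible.
#' @param relImprovement relative RMSE_CV improvement required to continue
#'   (default 0.005).
#' @param grid optional wavenumbers of the columns of `X` (defaults to
#'   column positions) used to report selected ranges.
#' @return list with `intervals` (an [IntervalSet-class]), `model` (the
#'   final [PLSModel-class] refitted on the selection), `metrics` (LOO
#'   metrics of the final model) and `history` (data.frame: round, window,
#'   rmseCv, accepted).
#' @export
forwardIpls <- function(X, y, candidates, maxIntervals = Inf, nLv = 6L,
                        relImprovement = 0.005, grid = NULL) {
  if (length(candidates) == 0L) stop("no candidate windows")
  X <- as.matrix(X)
  if (is.null(grid)) grid <- seq_len(ncol(X))
  n <- nrow(X)
  evalSubset <- function(idx) {
    k <- min(nLv, n - 2L, length(idx))
    looCv(X[, idx, drop = FALSE], y, k)
  }
  selectedWindows <- integer()
  selectedIdx <- integer()
  bestRmse <- Inf
  history <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    remaining <- setdiff(seq_along(candidates), selectedWindows)
    if (length(remaining) == 0L || length(selectedWindows) >= maxIntervals) {
      break
    }
    rmse <- vapply(remaining, function(w) {
      evalSubset(sort(unique(c(selectedIdx, candidates[[w]]))))$rmse
    }, numeric(1L))
    best <- which.min(rmse)
    improved <- if (is.infinite(bestRmse)) TRUE else {
      rmse[best] < bestRmse * (1 - relImprovement)
    }
    history[[round]] <- data.frame(
      round = round, window = remaining[best], rmseCv = rmse[best],
      accepted = improved
    )
    if (!improved) break
    selectedWindows <- c(selectedWindows, remaining[best])
    selectedIdx <- sort(unique(c(selectedIdx, candidates[[remaining[best]]])))
    bestRmse <- rmse[best]
  }
  if (length(selectedWindows) == 0L) stop("no window was accepted")
  ranges <- do.call(rbind, lapply(selectedWindows, function(w) {
    idx <- candidates[[w]]
    c(start = grid[min(idx)], end = grid[max(idx)])
  }))
  intervals <- methods::new("IntervalSet",
    ranges = ranges, indices = selectedIdx, wavenumbers = as.numeric(grid)
  )
  k <- min(nLv, n - 2L, length(selectedIdx))
  model <- fitPls(X[, selectedIdx, drop = FALSE], y, k,
                  variables = selectedIdx, wavenumbers = grid[selectedIdx])
  list(
    intervals = intervals,
    model = model,
    metrics = evalSubset(selectedIdx),
    history = do.call(rbind, history)
  )
}

#' Write / read an IntervalSet as a text table
#'
#' One row per window: start and end wavenumber (cm^-1) and the number of
#' grid variables the window resolves to.
#'
#' @param intervals an [IntervalSet-class].
#' @param path file path.
#' @param grid wavenumber grid to resolve against when reading.
#' @return `writeIntervalSet` returns `path` invisibly; `readIntervalSet`
#'   the restored [IntervalSet-class].
#' @export
writeIntervalSet <- function(intervals, path) {
  r <- intervalRanges(intervals)
  wn <- wavenumbers(intervals)
  nvar <- vapply(seq_len(nrow(r)), function(i) {
    sum(wn >= r[i, 1L] & wn <= r[i, 2L])
  }, integer(1L))
  df <- data.frame(start_cm1 = r[, 1L], end_cm1 = r[, 2L],
                   n_variables = nvar)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeIntervalSet
#' @export
readIntervalSet <- function(path, grid) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  resolveIntervals(grid, lapply(seq_len(nrow(df)), function(i) {
    c(df$start_cm1[i], df$end_cm1[i])
  }))
}
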