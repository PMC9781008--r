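# The parameter-recovery benchmark: 60 products in triplicate on the full
# 750-4000 cm-1 grid at 3.2 cm-1, analyte bands inside the three diagnostic
# windows, additive noise at 0.5% of the maximum noiseless mixture signal.
# Built lazily and cached so the acceptance blocks share one dataset.
recoveryConfig <- function(seed = 11L) {
  noiseless <- simulationConfig(
    nProducts = 60L, noiseSd = 0, baselineAmplitude = 0, scatterSd = 0,
    seed = seed
  )
  maxSignal <- max(absorbance(generateDataset(noiseless)))
  simulationConfig(nProducts = 60L, noiseSd = 0.005 * maxSignal, seed = seed)
}

recoveryEnv <- new.env()

recoveryRun <- function(seed = 11L) {
  key <- paste0("run_", seed)
  if (!is.null(recoveryEnv[[key]])) return(recoveryEnv[[key]])
  ds <- generateDataset(recoveryConfig(seed))
  prep <- preprocessPipeline(ds)
  split <- kennardStone(prep)
  cal <- subsetSamples(prep, calibrationIds(split))
  y <- sampleData(cal)$concentration
  wn <- wavenumbers(prep)
  sel <- forwardIpls(absorbance(cal), y, makeIntervals(wn, 30L, 10L),
                     nLv = 6L, grid = wn)
  out <- list(prep = prep, split = split, cal = cal, y = y, wn = wn,
              selection = sel)
  recoveryEnv[[key]] <- out
  out
}
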