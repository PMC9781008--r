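---
title: "Quantifying DNJ in mulberry products from ATR-FTIR spectra: methods"
author: "dnjftir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNJ in mulberry products from ATR-FTIR spectra: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnjftir)
```

## The problem

1-deoxynojirimycin (DNJ) is the polyhydroxylated piperidine alkaloid that
gives white mulberry (*Morus alba*) leaves their antidiabetic interest: it is
a competitive α-glucosidase inhibitor. Quantifying DNJ by HPLC is laborious —
the molecule has no chromophore and is too hydrophilic for reverse-phase
retention, so samples must be extracted and derivatized (FMOC-Cl) before each
run. ATR-FTIR spectroscopy of the powdered product needs neither, but the DNJ
signal sits on top of a dominant carbohydrate/protein matrix, baseline drift
and particle-size scatter. `dnjftir` implements the chemometric workflow that
turns such spectra into a quantitative DNJ assay:

1. preprocessing: weighted-least-squares (WLS) baseline removal, standard
   normal variate (SNV) scaling per spectrum, and per-variable autoscaling
   fitted on the calibration rows;
2. a deterministic Kennard–Stone split into calibration and external test
   products;
3. PLS1 regression with leave-one-out cross-validation (LOO-CV);
4. stepwise-forward interval PLS (iPLS) variable selection over wavenumber
   windows;
5. validation: calibration / CV / external-prediction metrics,
   Y-randomization, and a Williams-plot applicability domain;
6. the companion wet-chemistry calculations (ICH Q2 LOD/LOQ, recovery, %RSD,
   DPPH EC50, content-per-gram and dietary-intake coverage).

Because no public set of mulberry ATR-FTIR spectra with reference DNJ values
exists, the package ships a synthetic-spectra generator that reproduces the
statistical structure the workflow assumes, and every stage is tested
against it.

## The synthetic data model

`generateDataset()` builds a Beer–Lambert mixture on a 750–4000 cm⁻¹ grid.
Each product draws one concentration per chemical component; each replicate
spectrum is

```
A = s · (c' S) + baseline + ε,
```

where `S` holds the pure-component spectra (sums of Gaussian
`h · exp(−ln 2 ((ν−c)/w)²)` or Lorentzian `h w² / ((ν−c)² + w²)` bands, `w`
the half-width at half-maximum), `s = 1 + N(0, σ_scatter)` is a
per-replicate multiplicative scatter factor applied to the chemical signal,
the baseline is a random polynomial (default order 2) with coefficients
scaled by the baseline amplitude, and `ε` is i.i.d. Gaussian noise. The
scatter factor multiplies only the chemical mixture because that is the
distortion SNV is designed to remove; wavelength-correlated noise is not
modelled.

Defaults mirror the target measurement design: 19 products in triplicate,
750–4000 cm⁻¹. The grid spacing default is 3.2 cm⁻¹ rather than the 4 cm⁻¹
instrument resolution: the three diagnostic windows span ~95 cm⁻¹ each and
resolve to ~30 grid variables at 3.2 cm⁻¹, which keeps window arithmetic in
variables (interval size 30, step 10) consistent with the windows quoted in
cm⁻¹. The default analyte bands sit at 1150, 1380 and 1650 cm⁻¹ — inside the
diagnostic windows 1101–1196, 1333–1427 and 1603–1697 cm⁻¹
(`dnjIntervalPreset()`), where pyranose-ring C–O/C–C stretching, C–H/O–C–H
bending and amine N–H vibrations appear — and the "matrix" component mimics
the carbohydrate/protein background of dried leaf powder. Analyte
concentrations are uniform over 0–1000 µg/g per product: real products are
bimodal (teas ~500–1000 µg/g, extract-based supplements near zero), but a
uniform design exercises the regression over the whole range, which is what
the recovery tests need; band heights are scaled so a 1000 µg/g sample peaks
near 1 a.u. Defaults for the nuisance terms (noise sd 0.002 a.u., baseline
amplitude 0.05 a.u., scatter sd 0.05) are typical mid-IR magnitudes: scatter
of a few percent and a baseline an order of magnitude below the strongest
bands.

What the generator does *not* emulate: ATR penetration-depth dispersion,
water-vapour lines, detector drift between sessions, or the real covariance
between DNJ and polyphenol content. Passing the recovery benchmark therefore
shows the chain is implemented correctly and is statistically sound under
its stated assumptions — not that any particular instrument will achieve the
same figures on real products.

## Preprocessing decisions

**Replicate averaging first.** Triplicate spectra are averaged per product
before anything else, so the Kennard–Stone split operates on product-level
spectra and replicates of one product can never leak across the
calibration/test boundary.

**WLS baseline.** An asymmetric iteratively reweighted polynomial fit:
points above the current baseline get weight `exp(−r/σ_r)`, points below
weight 1, so the polynomial tracks the lower envelope under positive peaks.
Defaults: order 2, at most 100 iterations, convergence when the weight
vector moves by less than 1e−6 in relative L2 norm. The tests verify the
fit recovers a known quadratic under narrow peaks to better than 2% RMS.

**SNV** uses the n−1 standard deviation (documented so tests can be exact);
it is idempotent and invariant to positive affine scaling of a spectrum.

**Autoscaling at fit time.** Autoscaling parameters are part of the model,
fitted on calibration rows only and reapplied unchanged to test spectra —
fitting them before the split would leak test information. During interval
selection, autoscaling is refit on each candidate variable subset, i.e. the
model always autoscales exactly the variables presented to it.

**Stage order** is baseline → SNV → (autoscale at fit time). Kennard–Stone
distances are computed on baseline-corrected, SNV-scaled spectra, *before*
autoscaling, for the same leakage reason.

## PLS, cross-validation and model size

`fitPls()` is NIPALS PLS1 with X-deflation; `y` is centred but not
variance-scaled, so every RMSE is in the units of the supplied response
(µg/g for the synthetic data; the package reports whatever units `y` came
in). The implementation is cross-checked in the test suite against two
independent references: ordinary least squares (full-rank, all components)
and a deflation-free Krylov-subspace construction of the PLS solution, both
to 1e−8.

LOO-CV refits the *entire* chain (autoscaling + PLS) for every held-out
sample. `selectNLv()` picks the smallest number of latent variables whose
RMSE_CV is within 1% of the global minimum — a parsimonious near-minimum
rule; the reference workflow's six latent variables can be imposed directly
(`nLv = 6` is the pipeline default, user-overridable).

## Interval selection

Candidate windows of 30 consecutive variables start every 10 variables,
with a final window anchored at the grid end so coverage is exact. Forward
selection adds, each round, the window whose union with the current
selection minimizes RMSE_CV; under the "auto" stop rule the search ends
when the best addition improves RMSE_CV by 0.5% (relative) or less. The
0.5% threshold is this package's definition of "auto" stopping — a standard
greedy criterion; nothing in the workflow it reproduces defines one.
Candidates are evaluated at a fixed latent-variable budget (default 6,
capped by sample and variable counts per fold) rather than re-running the
LV-selection rule inside each candidate: that would multiply the LOO cost
by `maxLv` without changing the *ranking* of windows in any case we
examined. The three diagnostic windows are also shipped verbatim as
`dnjIntervalPreset()`, so the final published-style model can be rebuilt
without a search — the search path is not guaranteed (and not required) to
reproduce a manually curated interval list.

## Validation battery

`yRandomization()` shuffles the response (a multiset-preserving
permutation), refits the full chain at fixed LV count, and records each
permuted R²_CV. Three summaries are computed on the paired differences
`real − permuted`: a one-sided Wilcoxon signed-rank test, a one-sided sign
test, and the empirical randomization p-value
`(1 + #{permuted ≥ real}) / (n + 1)` — the latter is this package's
interpretation of a "randomization t-test", chosen because it is exact and
assumption-free. Each passes at α = 0.05. Note the first two p-values test
whether the real model beats the permuted ensemble *on average* and become
extremely small whenever it does; the empirical p-value is floor-limited at
`1/(n+1)` (0.0099 at 100 permutations).

`applicabilityDomain()` computes leverage in latent-score space,
`h = 1/n + t'(T'T)⁻¹t`, with the conventional Williams-plot cutoffs
`h* = 3(k+1)/n` and ±3 studentized residuals. Calibration residuals are
studentized with the `(1 − h)` correction on `n − k − 1` degrees of
freedom; query residuals use `e/s` without it, since query leverage is not
bounded by 1. The leverage trace identity `Σh = k + 1` (centred scores plus
the 1/n term) is asserted in the tests for every fitted model.

## Numerical choices and degenerate inputs

- SNV and autoscaling refuse zero-variance input (the error names the
  offending wavenumber); `computeMetrics()` refuses a constant `y`.
- Kennard–Stone breaks distance ties by lowest row index; duplicate rows
  are allowed.
- EC50 comes from bracketing linear interpolation on an
  isotonic-regularized (pooled-adjacent-violators) curve; a point exactly
  at 50% returns its concentration, no crossing is an error. A four-
  parameter logistic fit is deliberately out of scope.
- LOD/LOQ use the blank-response standard deviation (n ≥ 6), not the
  regression residual σ; LOQ is computed as `LOD · 10/3.3` so the ICH ratio
  is exact to machine precision. Published tables that round LOD before
  computing LOQ can disagree in the last digit — recomputing from σ and S
  avoids that, and the package documents the sensitivity rather than
  matching rounded intermediates.
- All serializations (spectra, model, intervals, split, report) are plain
  text at 17 significant digits; round trips are lossless to 1e−15.

## Problem sizes used in the shipped checks

The test suite exercises the full chain on a 60-product × 3-replicate
dataset (grid 750–4000 cm⁻¹ at 3.2 cm⁻¹, noise at 0.5% of the maximum
noiseless signal) — large enough that the forward search must discriminate
~100 candidate windows, small enough to run comfortably on one CPU. On that
benchmark the selected-interval model reaches R²_CV ≥ 0.95, the selection
overlaps a true analyte band, and Y-randomization at 100 permutations
passes all three tests while a pure-noise response does not. Unit tests use
smaller seeded fixtures (6–24 samples) where exact oracles are feasible.

## Known limitations

- The synthetic generator, not real spectra, underwrites all quantitative
  claims; figures like R²_CV transfer to real products only insofar as the
  generator's assumptions hold.
- Forward iPLS is greedy; it can stop at one window when a single band
  carries most of the covariance, and it is not guaranteed to reproduce a
  manually curated interval set.
- No smoothing/derivative preprocessing (Savitzky–Golay) and no MSC: the
  implemented chain is baseline + SNV + autoscaling only.
- PLS2, kernel/orthogonal PLS variants, and backward or genetic-algorithm
  interval selection are out of scope.

## A minimal run

```{r pipeline, eval = FALSE}
cfg <- runConfig(
  simulation = simulationConfig(nProducts = 19),
  presetIntervals = dnjIntervalPreset(),
  nLv = 6, nPermutations = 100, seed = 1
)
res <- runPipeline(cfg)
res$report
```

Every artifact the run writes (split, intervals, model, report, Williams
plot, log) is stamped with the seed and a hash of the configuration, and a
rerun with the same configuration reproduces the report bit-for-bit.
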