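# subnucq

Quantification of subnuclear protein localization and mobility from
three-channel confocal imaging, fluorescence correlation spectroscopy
(FCS) and fluorescence recovery after photobleaching (FRAP), written for
cell biologists studying nucleolar enrichment of nuclear proteins (e.g.
Snail-family transcription factors).

Nucleoli are dense bodies that partially exclude even inert fluorescent
proteins — about half of a free mCherry signal survives inside them — so a
naive nucleolus/nucleoplasm intensity ratio confounds genuine binding with
volume exclusion. `subnucq` implements:

* **Imaging** — a staged nucleolar segmentation pipeline (mode
  normalization, marker/reference ratio threshold 2.0, column-profile
  normalization with an 11-px boxcar, normalized-marker threshold 1.4,
  per-nucleolus full-width-half-minimum refinement on the 200-nm-smoothed
  reference channel) and enrichment statistics. The **adjusted
  nucleolus/nucleoplasm ratio** corrects for inaccessible volume with the
  through-origin least-squares slope over nucleolar pixels,

  `R̂ = Σ Fᵢ fᵢ / Σ fᵢ²`,  reported as `R̂ − 1`,

  where `Fᵢ` is the normalized construct and `fᵢ` the normalized
  free-reference intensity (accessible-volume map); a reference-like
  construct scores 0. Cytoplasm/nucleoplasm ratios are
  reference-normalized medians.
* **Co-localization** — kernel-smoothed scatter plots of paired nucleolar
  pixel intensities (with a disrupted-nucleolus mode that keeps only
  pixels above the nucleoplasm level) and bilinear line profiles.
* **FCS** — multiple-tau autocorrelation of photon traces with segment
  quality control, fitting of
  `G(τ) = (1/N)[1 + T/(1−T) e^(−τ/τ_Trip)](1+τ/τ_Dif)⁻¹(1+τ/(a²τ_Dif))^(−1/2)`
  under the cellular bounds (τ_Dif ≥ 200 µs, τ_Trip ≤ 150 µs, structure
  parameter fixed to the calibration value 8), conversion
  `D = D_ref·τ_ref/τ_Dif` with the buffer calibration (0.14 ms,
  90 µm²/s), and concentrations from
  `V = a(4π D_ref τ_ref)^{3/2} ≈ 0.504 fL`.
* **FRAP** — scan-bleach correction (double exponential × step),
  FLIP-step removal, double-exponential recovery fits
  `1 − a₁e^(−t/τ₁) − a₂e^(−t/τ₂)`, and 207-nm concentric-ring radial
  profiles.
* **Synthetic data** — cell phantoms, FCS curves / Brownian photon
  traces and FRAP traces / conservative diffusion movies with known
  ground truth, including named presets keyed to the published
  enrichment ratios and recovery constants.

## Worked example

```r
library(subnucq)
cells   <- simulateCells("SNAILA-FL", n = 20, seed = 1)  # phantom population
summary <- quantifyPopulation(cells)                      # full pipeline
summary
#> RatioSummary over 20 cell(s), 52 nucleoli
#>   cytoNpRaw    0.896  [0.854, 0.939]  (n = 20)
#>   cytoNpNorm   0.199  [0.198, 0.200]  (n = 20)
#>   rawRatio     1.677  [1.572, 1.782]  (n = 20)
#>   adjustedRatio 2.356  [2.140, 2.572]  (n = 20)
```

Reading the output: the free-reference channel's raw cytoplasm/nucleoplasm
ratio recovers the preset 0.89; the construct's normalized ratio of 0.2
means five-fold nucleoplasmic enrichment over the reference; the raw
nucleolar ratio 1.68 ≈ (1+R)·f mixes enrichment with accessible volume,
and the adjusted ratio ≈ 2.36 recovers the generator's mean enrichment
R = 2.46 up to the estimator's known −4% partial-volume bias, with a 95%
confidence interval from the per-cell spread.

An FCS fit in three lines:

```r
sim <- makeACF(fcsSimSpec(params = "calibration", noiseSdRel = 0.02, seed = 1))
fit <- fitACF(sim$curve, tauDifLower = 0)   # calibration-style: bound lifted
toDiffusionCoefficient(coef(fit)[["tauDif"]])  # ~90 um^2/s
```

A command-line wrapper is installed at `inst/scripts/subnucq.R`
(subcommands `simulate`, `ratio`, `coloc`, `fcs-fit`, `frap-fit`,
`report`).

## Documentation

The methods vignette (`vignettes/subnucq-methods.Rmd`) describes the
models, the numerical choices (mode binning, partial-volume guard, fit
bounds, segment quality control, antithetic replicate design), and what
the synthetic validation does and does not demonstrate about real data.
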