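# Named presets for the synthetic generators. The enrichment values and
# population spreads are the study conditions the estimators are validated
# against; spreads are back-calculated from the printed 95% CIs
# (sd = halfwidth * sqrt(n) / t_{0.975, n-1}).

.cellPresets <- list(
  "mCherry-free" = list(
    enrichmentR = 0.00, enrichmentSd = 0.00,
    cytoNpRef = 0.89, cytoNpRefSd = 0.084,    # 0.89 +/- 0.01, n = 275
    cytoNpConstructNorm = 1.0),
  "SNAILA-FL" = list(
    enrichmentR = 2.46, enrichmentSd = 0.632, # 2.46 +/- 0.25, n = 27
    cytoNpRef = 0.89, cytoNpRefSd = 0.084,
    cytoNpConstructNorm = 0.2),
  "SNAILB-FL" = list(
    enrichmentR = 0.90, enrichmentSd = 0.260, # 0.90 +/- 0.15, n = 14
    cytoNpRef = 0.89, cytoNpRefSd = 0.084,
    cytoNpConstructNorm = 0.2),
  "HsSNAIL1" = list(
    enrichmentR = 0.27, enrichmentSd = 0.245, # 0.27 +/- 0.09, n = 31
    cytoNpRef = 0.89, cytoNpRefSd = 0.084,
    cytoNpConstructNorm = 0.2),
  "HsSNAIL2" = list(
    enrichmentR = 0.52, enrichmentSd = 0.250, # 0.52 +/- 0.09, n = 32
    cytoNpRef = 0.89, cytoNpRefSd = 0.084,
    cytoNpConstructNorm = 0.2),
  "SNAILA-d5SNAG" = list(
    enrichmentR = 0.45, enrichmentSd = 0.142, # 0.45 +/- 0.09, n = 12
    cytoNpRef = 0.89, cytoNpRefSd = 0.084,
    cytoNpConstructNorm = 0.2),
  "SNAILA-dZnf" = list(
    enrichmentR = 0.32, enrichmentSd = 0.066, # 0.32 +/- 0.04, n = 13
    cytoNpRef = 0.89, cytoNpRefSd = 0.084,
    cytoNpConstructNorm = 0.9),               # zinc-finger loss: cytoplasmic
  "DRB-disrupted" = list(
    enrichmentR = 1.2, enrichmentSd = 0.3,
    cytoNpRef = 0.89, cytoNpRefSd = 0.084,
    cytoNpConstructNorm = 0.2, fragmented = TRUE)
)

# FCS presets: diffusion times chosen so the calibration conversion
# D = DRef * tauRef / tauDif lands in the reported per-compartment ranges.
.fcsPresets <- list(
  "calibration"      = list(N = 10, T = 0.15, tauTrip = 30e-6,
                            tauDif = 0.14e-3, a = 8),  # D = 90 um^2/s
  "mTq2-nucleoplasm" = list(N = 25, T = 0.15, tauTrip = 30e-6,
                            tauDif = 0.548e-3, a = 8), # D ~ 23 um^2/s
  "FL-nucleoplasm"   = list(N = 25, T = 0.15, tauTrip = 50e-6,
                            tauDif = 8.4e-3, a = 8),   # D ~ 1.5 um^2/s
  "dZnf-nucleoplasm" = list(N = 25, T = 0.15, tauTrip = 50e-6,
                            tauDif = 3.15e-3, a = 8),  # D ~ 4 um^2/s
  "FL-nucleolus"     = list(N = 25, T = 0.15, tauTrip = 50e-6,
                            tauDif = 36e-3, a = 8)     # D ~ 0.35 um^2/s
)

# FRAP recovery presets: the double-exponential parameters reported for
# nucleolar and nucleoplasmic bleaches.
.frapPresets <- list(
  "nucleolus"   = list(a1 = 0.46, tau1 = 1.98, a2 = 0.18, tau2 = 11.12,
                       stepLoss = 0.12, bleachDepth = 0.64,
                       immobileFraction = 0),
  "nucleoplasm" = list(a1 = 0.31, tau1 = 1.31, a2 = 0.23, tau2 = 7.37,
                       stepLoss = 0.12, bleachDepth = 0.54,
                       immobileFraction = 0)
)

#' Named simulation presets
#'
#' Parameter bundles for the synthetic generators, keyed to the reported
#' enrichment ratios, diffusion times and FRAP recovery constants.
#'
#' @param type one of `"cell"`, `"fcs"`, `"frap"`.
#' @param name preset name; omit to list available names.
#' @return a named list of preset parameters, or a character vector of
#'   preset names when `name` is missing.
#' @examples
#' presetTable("cell")
#' presetTable("cell", "SNAILA-FL")$enrichmentR
#' @export
presetTable <- function(type = c("cell", "fcs", "frap"), name = NULL) {
  type <- match.arg(type)
  tab <- switch(type, cell = .cellPresets, fcs = .fcsPresets,
                frap = .frapPresets)
  if (is.null(name)) return(names(tab))
  if (!name %in% names(tab))
    stop("unknown ", type, " preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "))
  tab[[name]]
}
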