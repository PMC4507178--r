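Package: subnucq
Title: Quantification of Subnuclear Localization and Mobility from
    Confocal Imaging, FCS and FRAP
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of subnuclear protein localization and
    mobility from three-channel confocal images, fluorescence correlation
    spectroscopy (FCS) and fluorescence recovery after photobleaching
    (FRAP). Implements a nucleolar segmentation and normalization pipeline
    producing cytoplasm/nucleoplasm and inaccessible-volume-corrected
    ("adjusted") nucleolus/nucleoplasm enrichment ratios; pixel-level
    co-localization scatter and line-profile analysis; one-component 3-D
    diffusion plus dark-state autocorrelation model fitting with
    calibration to apparent diffusion coefficients and concentrations;
    and FRAP trace correction, double-exponential recovery fitting and
    radial-profile mobility analysis. A synthetic-data generator provides
    cell phantoms, FCS curves/traces and FRAP traces/movies with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    EBImage,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, Visualization, Preprocessing
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'coloc.R'
    'config.R'
    'fcs-sim.R'
    'fcs.R'
    'frap-sim.R'
    'frap.R'
    'imgquant.R'
    'io.R'
    'phantom.R'
    'pipeline.R'
    'presets.R'
    'subnucq-package.R'
    'utils.R'
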