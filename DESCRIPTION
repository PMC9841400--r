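Package: CondensateKit
Title: Quantification of Biomolecular Condensates in Cells and In Vitro
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying liquid-like biomolecular condensates
    from fluorescence microscopy and companion biochemical assays: nuclear
    foci detection on maximum-intensity projections with adaptive local
    thresholding, per-nucleus focus counting and foci-positive cell
    classification, single-exponential FRAP (fluorescence recovery after
    photobleaching) fitting with double normalization yielding half-times
    and mobile fractions with population confidence intervals, in vitro
    droplet counting and Manders colocalization on fixed-range thresholds,
    turbidity (OD340) and dose-response summaries with saturation
    concentration estimation, densitometry standard-curve concentration
    estimation, and the associated statistical reporting (one-way ANOVA,
    unpaired two-tailed t tests, significance stars). A synthetic-data
    module generates image stacks, recovery traces, droplet fields,
    turbidity series and standard curves with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'densitometry.R'
    'utils.R'
    'droplet-quant.R'
    'foci-quant.R'
    'frap-kinetics.R'
    'io.R'
    'stats-report.R'
    'synthetic-data.R'
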