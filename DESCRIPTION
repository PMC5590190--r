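Package: panelval
Title: Analytical Validation Toolkit for Targeted Cancer Sequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variant detection and analytical validation for hybrid-capture
    targeted tumor sequencing panels. Implements a threshold filter cascade
    for somatic SNV and indel calling from tumor/matched-normal pileup
    counts (minimum depth, normal-control allele fraction, strand bias, and
    allele-fraction cutoffs with hotspot relaxation), matched-normal
    log2-ratio copy-number calling with GC-bias correction and BIC-guided
    segmentation, and rearrangement detection from clipped reads and
    discordant read pairs. A synthetic-data generator emulates germline and
    cancer-cell-line variant pools, stranded pileups, tumor-purity dilution
    series, and junction-spanning read pairs, so every stage is testable
    without external data. A validation engine computes sensitivity-versus-
    depth curves per allele-fraction bin by in-silico downsampling, plateau
    depths, copy-number limit-of-detection over a purity dilution grid, and
    2x2 concordance statistics against orthogonal assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
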