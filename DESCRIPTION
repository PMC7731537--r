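Package: glntrace
Title: In Vivo 13C-Glutamine Stable-Isotope-Resolved Metabolomics of the
    TCA Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for in vivo 13C-glutamine stable
    isotope-resolved metabolomics (SIRM) of bone marrow plasma cells.
    Predicts first-turn TCA-cycle isotopologue mass shifts by positional
    carbon tracking of a glutamine tracer, corrects GC-MS selected-ion
    monitoring mass isotopomer distributions for natural isotope
    abundance using nonnegative least squares, computes mole percent
    enrichment and precursor-normalized relative enrichments, contrasts
    paired CD138+ plasma cells against CD138- mononuclear cells, fits
    internal-standard calibration curves for absolute quantitation, and
    generates synthetic cohorts with the statistical structure of
    tracer-infusion studies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
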