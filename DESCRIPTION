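Package: isodrift
Title: Stable-Isotope Bookkeeping and Drift Diagnostics for In-Extract
    Enzymatic Activity in Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and characterizing protein-mediated
    metabolite interconversion in resuspended metabolomics extracts.
    Provides exact monoisotopic mass and adduct m/z calculation for
    isotope-labeled metabolites, combinatorial isotopologue
    distributions, a label-resolved mass-action simulator of the
    transaminase futile cycle (glutamate + oxaloacetate <->
    alpha-ketoglutarate + aspartate) with deuterium, carbon-13 and
    nitrogen-15 bookkeeping, an LC-MS observation model for repeat
    injection series, internal-standard and label-ratio quantitation
    with tracer-atom molar balance accounting, repeat-injection drift
    statistics (spline trend tests, PCA path length, set
    intersections, hydrophobicity-recovery correlation), and
    fragment-ion screening of MS2 spectra with chromatographic peak
    filters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    splines,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
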