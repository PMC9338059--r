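Package: doseimpact
Title: Dose-Response Analysis for Isothermal Thermal Proteome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of isothermal dose-response thermal proteome profiling
    (ITDR-TPP) and phosphoproteomics experiments for kinase-inhibitor target
    deconvolution. Dose-response traces are smoothed with a Gaussian
    (Nadaraya-Watson) kernel estimator on ordinal dose positions and
    summarised by their average slope; phosphosite curves are classified as
    hyper-phosphorylated, hypo-phosphorylated, biphasic or non-responsive
    from run-length statistics of the fitted curve, with replicate
    concordance required for a final call. Includes readers for
    MaxQuant-like quantification tables, protein-level impact maps at two
    temperatures with slope-threshold hit calling, hypergeometric gene-set
    enrichment, a synthetic-data generator with known ground-truth response
    labels, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
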