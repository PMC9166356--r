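Package: steadyflux
Title: Constraint-Based Metabolic Modelling with Transcriptomic and
    Transposon-Insertion Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, validating and interrogating small
    genome-scale metabolic models. Implements flux balance analysis (FBA),
    parsimonious FBA, flux variability analysis and carbon-source phenotype
    screening on a built-in bounded-simplex linear-programming core;
    gene-protein-reaction (GPR) boolean logic and in-silico gene-deletion
    essentiality calling; a transposon insertion sequencing (TraDIS)
    essentiality caller based on curated insertion indexes and
    reference-anchored percentile thresholds; iMAT-style integration of
    RPKM expression data via a mixed-integer program to derive
    condition-specific models; hit-and-run flux sampling with
    Kolmogorov-Smirnov differential-flux statistics, bootstrap confidence
    intervals and transcriptional/post-translational regulatory
    classification; and generators for fully synthetic benchmark inputs
    (toy network, expression tables, insertion libraries, biomass curves)
    with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
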