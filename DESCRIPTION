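Package: crossmir
Title: Cross-Platform miRNA Microarray Concordance and Probe Thermodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for comparing miRNA expression measurements across two
    microarray platforms and a qPCR arm: nearest-neighbor RNA/DNA hybrid
    thermodynamics (duplex free energy at 37 C and formamide/salt-corrected
    melting temperature) for probe panels, vendor-style normalization
    (quantile, 75th-percentile scaling, negative-signal clamping, replicate
    spot summarisation), detection calling and overlap accounting against a
    shared feature universe, Welch's t-test differential expression with a
    compound significance filter, Pearson-distance hierarchical clustering
    with Newick export, delta-delta-Ct qPCR fold changes, GC-content
    discordance diagnostics, and a synthetic two-platform data generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    ape,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
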