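Package: drwhite
Title: Simulation and Analysis of DR-white Single Double-Strand Break
    Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying DNA double-strand break (DSB) repair with
    the Drosophila DR-white I-SceI reporter. Simulates amplicon
    sequencing reads of repair products with configurable mixtures of
    homologous recombination (HR), non-homologous end joining (NHEJ) and
    microhomology-mediated end joining (MMEJ) outcomes; calls repair
    junctions with left-aligned indels and microhomology detection;
    classifies repair pathways with the cut-site proximity filter and
    size/microhomology thresholds used in single-DSB reporter studies;
    decomposes aggregate Sanger-style traces into indel spectra by
    non-negative least squares; summarises DSB focus movement and
    resolution kinetics relative to polycomb bodies; and quantifies
    ChIP-qPCR enrichment by the delta-delta-Ct method with spike-in
    specificity controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    pracma,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
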