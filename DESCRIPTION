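Package: anis
Title: Hierarchical Informational Structure of Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the ANIS (ANalysis of Informational Structure) method
    for revealing the hierarchical organization of protein sequences. From a
    pentapeptide occurrence table built over a non-redundant protein sequence
    collection, each protein is mapped to a total-frequency profile, a
    Gaussian-smoothed distribution, and an inscribed-Gaussian height field
    over a triangular scale-space domain. Level-wise local maxima of the
    height field form a tree of hierarchical ELements of Informational
    Structure (ELIS); Shannon-entropy deviation curves locate branch points;
    and across a protein cohort, a correlation matrix of entropy-derivative
    vectors with continuous-square-area (CSA) detection identifies
    characteristic hierarchy scales. Includes synthetic-data generators with
    planted structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
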