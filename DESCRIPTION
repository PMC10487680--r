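Package: pprdesign
Title: Design and Screening Toolkit for Retargeted Pentatricopeptide
    Repeat Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and screening libraries of retargeted
    pentatricopeptide repeat (PPR) proteins of the restorer-of-fertility
    class. Implements PPR-code based scoring of RNA binding sites
    (position-specific scoring matrices built from position 5/35 residue
    pairs), strand-aware scans of linear or circular transcript and
    genome sequences, combinatorial variant-library enumeration,
    Gibson-assembly fragment tiling with in-silico reassembly checks,
    allele-discriminating qPCR primer design with a nearest-neighbour
    melting-temperature model, plate-image leaf-area quantification and
    bimodal growth classification, delta-delta-Ct relative expression,
    cleavage-site coordinate arithmetic, and seeded synthetic-data
    generators covering every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    farver,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
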