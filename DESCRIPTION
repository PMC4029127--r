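Package: wheatmir
Title: miRNA Discovery and Expression Profiling from Wheat Small RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for identifying known, novel and candidate
    microRNAs from multi-tissue small RNA sequencing libraries of wheat.
    Implements adapter/length/repeat read cleaning and unique-tag collapsing,
    exact genome matching, ncRNA contaminant removal at 90 percent identity,
    exact-match known-miRNA assignment with conservation classing,
    MIREAP-style hairpin precursor validation with miRNA* duplex criteria,
    reads-per-million expression profiling with tissue-preference classes,
    expectation-score target prediction with site-accessibility filtering,
    and delta-delta-CT qPCR concordance analysis. A synthetic-data module
    generates toy genomes with planted MIRNA hairpins and five tissue
    libraries with full ground truth so the whole pipeline is testable
    offline. RNA secondary structure is computed with ViennaRNA's RNAfold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: ViennaRNA (RNAfold on PATH)
Config/testthat/edition: 3
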