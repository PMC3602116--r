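Package: tissuesam
Title: Tissue-Enriched Expression and Permutation-Based Differential
    Expression for One-Color Oligonucleotide Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for one-color oligonucleotide microarray
    expression data from multiple brain tissues: probe-to-gene collapse with
    trimmed averaging, background correction, log2 transformation and
    quantile normalization; SAM-style moderated t statistics with
    permutation-estimated false discovery rates and delta-threshold calling;
    cross-tissue enrichment scoring with blood-contamination exclusion and
    expected-versus-observed enrichment counts; and RT-PCR relative
    quantification by the 2^-deltaCt method with nonparametric group tests.
    Includes a synthetic-data generator with planted differential-expression,
    tissue-enrichment and blood-contaminant signals so every stage is
    testable without external data, plus readers and writers for simple
    tab-delimited dialects and GEO series-matrix files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    limma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
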