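Package: tcrgamma
Title: Germline Annotation, Amplicon Simulation and Repertoire Analysis
    for the Chicken TCR Gamma Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing the T cell receptor gamma (TCRg)
    chain repertoire from 5' RACE amplicon sequencing. Models germline
    V/J/C gene segments with IMGT-style functionality classification,
    recombination signal sequence (RSS) scanning and 70%-identity
    subgroup clustering; provides a windowed-identity dot-plot operator
    with tandem-duplication run detection; simulates V-J recombination
    with exonuclease trimming, N/P nucleotide insertion and paired-end
    read emission; implements the read-processing chain (pair merging,
    barcode demultiplexing, seeded V/J assignment, CDR3 motif
    extraction, productivity filtering, clonotype dereplication); and
    summarizes repertoires (segment usage, V-J pairing, CDR3 length and
    amino-acid composition with an ultralong split, retention
    reporting).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
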