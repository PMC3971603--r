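Package: otuforge
Title: De Novo Assembly of Operational Taxonomic Units from
    Protein-Coding Amplicon Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forms operational taxonomic units (OTUs) from protein-coding
    barcode amplicon reads (such as the cpn60 universal target) by de novo
    assembly rather than reference clustering.  Provides a greedy
    overlap-layout-consensus assembler with exact internal read tracking, a
    de Bruijn graph assembler, an exact dynamic-programming read mapper for
    per-library OTU abundance, split-end chimera screening against a
    reference set, reading-frame identification and collapse of nucleotide
    OTUs to non-redundant peptide OTUs, rarefaction by down-sampling to the
    smallest library, assembly quality metrics (per-OTU sensitivity and
    specificity, compositional error), and a seeded synthetic-community
    read simulator with per-read ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
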