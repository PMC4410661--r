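Package: mosaicmatch
Title: Ultra-Fast Protein Domain Classification by Mosaic Matching of
    Oligopeptide Words
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free assignment of protein and DNA sequences to
    protein domain families. Reference sequences are decomposed into
    18-residue oligopeptide words stored in a sorted dictionary under an
    evolutionary amino-acid alphabet ordering; query words are classified
    by longest-common-prefix nearest-neighbour lookup and scored with
    position-specific scoring matrices learned by regularized least
    squares. Overlapping word scores are combined per residue into a
    mosaic score per family, and length-dependent noise thresholds are
    calibrated empirically on random sequences at fixed false-positive
    rates. Includes six-frame ORF extraction for DNA input, a synthetic
    protein-family generator for testing, and command-line style drivers
    for database construction and classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
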