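Package: flasmr
Title: Fixed-Length Approximate String Matching for Biological Sequences
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bit-parallel dynamic programming for fixed-length approximate
    string matching: find all factors of a text within a distance threshold
    of any fixed-length factor of a pattern, under the Hamming and edit
    distance models, in time independent of the threshold and of the
    alphabet and for factor lengths far beyond the machine word. On top of
    the cores the package provides approximate circular string matching by
    pattern doubling, refinement of circular sequence rotations for multiple
    alignment, single and structured motif extraction with quorum over
    MultiFASTA input, and the Chang-Marr q-gram distance index built from a
    de Bruijn sequence, together with seeded synthetic-data generators and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
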