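Package: kbasealign
Title: Local Alignment of Generalized k-Base Encoded DNA Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generalized k-base (color-space) encoding and decoding of DNA
    sequence, in the style of SOLiD two-base encoding extended to k
    simultaneously observed bases, together with a context-indexed
    Smith-Waterman dynamic programming aligner with affine gap penalties
    that aligns an encoded read to a DNA reference while distinguishing
    encoding (color) errors from true base substitutions (SNPs). Includes
    scoring-scheme validity constraints and SNP-preference scenario
    classification for 5-base encoding, a brute-force alignment oracle for
    testing, and a seeded simulation framework that measures alignment
    power and false positive / false negative SNP discovery rates under
    uniform and position-dependent color error models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
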