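Package: bitalign
Title: Bit-Parallel Pairwise Sequence Alignment Under General Integer Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes optimal global and semi-global pairwise alignment
    scores under a general integer scoring scheme (match M >= 0, mismatch
    I < 0, gap G < 0 with I >= 2G) using bit-parallel dynamic programming.
    Scores are never materialized; only the vertical and horizontal
    difference values between adjacent cells of the scoring matrix are
    kept, packed column-wise into machine words so that a whole word of
    cells is advanced per logic or addition operation.  Two engines are
    provided: a standard representation with one bit vector per distinct
    difference value, and a packed representation that spreads the binary
    digits of value offsets across bit planes so all columns can be added
    simultaneously.  A per-weight-set program generator emits the
    specialized straight-line word program, interprets it, and counts
    operations for efficiency reporting.  Classical dynamic-programming
    oracles, a seeded synthetic fixture generator, FASTA batch scoring and
    a small command-line driver are included for verification and use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
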