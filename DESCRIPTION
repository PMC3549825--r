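Package: uasub
Title: Alignment-Free Genome Phylogeny from Underlying Common Subwords
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Alignment-free comparison of whole nucleotide genomes through
    matching statistics and common subwords.  The package discovers the
    irredundant common subwords of a sequence pair with a generalized
    suffix-array index, filters them to the non-overlapping "underlying" set
    by a length-then-first-occurrence priority rule, and turns the selected
    subwords into a symmetric, length-normalized distance (d_UA).  Matching
    is optionally extended to inversions and base complements by indexing an
    extended target sequence.  Distance matrices feed a deterministic
    neighbor-joining tree builder, and reconstructed topologies can be
    compared with Robinson-Foulds and triplet distances.  A synthetic-genome
    generator with a known phylogeny and planted inversion/complement events
    makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
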