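Package: codonfold
Title: Coding Sequence Design by Joint Optimization of RNA Structure Stability and Codon Usage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs mRNA coding sequences (CDSs) for a given protein by
    jointly optimizing secondary-structure stability (minimum free energy,
    MFE) and codon usage (codon adaptation index, CAI). All synonymous CDSs
    are represented compactly as a codon-prefix lattice, and a Zuker-style
    dynamic program over (position, codon-prefix) states finds the CDS and
    structure minimizing a weighted combination of folding free energy and
    per-codon log relative adaptiveness, exactly or with beam-search
    pruning. Supported Pareto-optimal trade-offs between MFE and CAI are
    enumerated automatically by recursive weighted-sum scalarization.
    Includes a simplified Turner 2004 nearest-neighbor energy model, a
    Nussinov base-pair maximization model, brute-force oracles for
    validation at small scale, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
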