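Package: hopcode
Title: Error-Minimizing Genetic Codes from Hopfield Network Tours
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying mutational error minimization in genetic
    codes. Implements the amino-acid physio-chemical index table with
    z-score normalization, the standard genetic code and codon-level
    mutation utilities, a transversion-minimizing codon wheel that maps
    amino-acid tours onto 64 codons, a transition-weighted mutational
    error statistic with a synonymous-block permutation null, and a
    normalized (mean-field) Hopfield network with simulated annealing
    that solves the 21-city amino-acid traveling salesman problem to
    generate candidate error-minimizing codes. Includes experiment
    drivers for optimization ensembles, index PCA and correlation
    diagnostics, and deterministic fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
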