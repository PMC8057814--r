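Package: epiland
Title: Global Epistasis on Sparse Fourier Fitness Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying global diminishing-returns and increasing-costs
    epistasis as an emergent property of genotype-fitness maps with widespread
    microscopic epistasis. Represents fitness landscapes as sparse Fourier
    (Walsh) expansions over biallelic loci, computes exact locus-level
    epistasis statistics (variance fractions, additivity of interacting loci,
    pairwise epistatic overlap), generates "connectedness"-model landscapes in
    which loci participate in random interaction pathways, simulates
    strong-selection weak-mutation adaptive walks, evaluates the analytic
    distribution of fitness effects and its long-time adaptation scaling laws,
    and estimates global-epistasis statistics from mutant-by-background
    fitness panels of the kind produced by large barcoded fitness assays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
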