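Package: codonscape
Title: Rare-Event Sampling of the Genetic Code Fitness Landscape
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to analyse the translational-error robustness landscape of
    the genetic code. Implements the misreading-cost model on the standard
    64-codon table with transition/transversion-weighted single-base errors
    and a squared polar-requirement penalty, exact inclusion-exclusion
    counting of the constrained random-code ensemble, naive and
    block-structure reference samplers, Wang-Landau training of
    multicanonical weights with fixed-weight multicanonical Monte Carlo for
    density-of-states estimation down to tail densities of order 1e-20,
    a truncation-selection genetic algorithm with path-dependence
    diagnostics, and landscape reconstruction by PCA and k-means with elbow
    selection. Small enumerable toy codon systems provide exact oracles for
    every stochastic stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, graphics, Rcpp, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), Biostrings, yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'bignum.R'
    'code-model.R'
    'cost-model.R'
    'sampling.R'
    'multicanonical.R'
    'ga.R'
    'landscape.R'
    'synthetic.R'
    'serialization.R'
    'pipeline.R'
    'show-methods.R'
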