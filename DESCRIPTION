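Package: infoLattice
Title: Simplicial Information Landscapes for Multivariate Dependence Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Estimates joint probabilities from binned real-valued data
    matrices and computes Shannon information quantities (joint entropies,
    multivariate mutual information, total correlation, conditional
    quantities and eta decompositions) over the full simplicial lattice of
    variable subsets. Provides information landscapes, extremal information
    paths with a first-minimum stopping rule, an undersampling-dimension
    estimate, and a marginal-preserving shuffle test of k-dependence, with
    synthetic generators (extremal binary triples, independent and Markov
    nulls, planted dependent modules, two-population designs) for
    validation. Intended for exploratory analysis of higher-order
    statistical interactions in omics-style sample-by-variable matrices
    such as single-cell gene expression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'discretize.R'
    'measures.R'
    'landscape.R'
    'paths.R'
    'stats.R'
    'fixtures.R'
    'io.R'
    'pipeline.R'
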