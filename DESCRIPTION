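Package: cytonuclear
Title: Tree-Set Concordance Analysis for Cytonuclear Discordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying concordance between sets of phylogenetic
    trees derived from different genomic compartments, motivated by the
    conflict between mitochondrial and nuclear histories observed in rapid
    radiations such as Myotis bats. Provides bipartition algebra
    (Robinson-Foulds distances, majority-rule consensus with bipartition
    frequencies, topology census), Robinson-Foulds tree-space embedding by
    classical multidimensional scaling with hexagonal binning, normalized
    quartet scores of a species tree against gene-tree sets, supermatrix
    construction regimes (completeness thresholds, length bins, random
    subsamples), statistical binning of gene trees into balanced compatible
    supergene bins, a transparent Jukes-Cantor + neighbor-joining gene-tree
    estimator with an average-internode-distance species-tree summary, and a
    multispecies-coalescent simulator with introgression for generating
    synthetic data with realistic discordance and missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
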