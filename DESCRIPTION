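Package: matenet
Title: Species Delimitation from Mating and Relatedness Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delimits sympatric, hybridizing species by the interfertility
    criterion of the biological species concept. Builds undirected mating
    networks from exclusion-based paternity assignment of open-pollinated
    progeny, builds relatedness networks from thresholded Queller-Goodnight
    pairwise relatedness estimates, and clusters either network with a
    continuous (mixed-membership) stochastic block model in which every
    individual is a simplex mixture of a few extremal hypothetical nodes, one
    of them structurally unconnected. Maximum-likelihood fitting with AIC
    model selection, triangular classification of individuals into two pure
    species plus an intermediate class, congruence summaries across
    delimitation criteria, and a logistic-regression test of the allospecific
    neighbourhood effect on assignment congruence. Includes a synthetic
    two-species forest-stand generator (spatial positions, multilocus SSR
    genotypes, distance-decaying pollen dispersal, partial interspecific
    compatibility, pollen immigration) so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
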