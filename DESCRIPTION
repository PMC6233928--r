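Package: introgsim
Title: Forward Simulation of Introgression Under Deleterious Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discrete-generation Wright-Fisher forward simulator for studying
    how deleterious variation (the distribution of fitness effects, dominance,
    recombination rate, demography, and mating system) shapes the genomic
    landscape of introgressed ancestry after a single admixture pulse.
    Includes a synthetic genome-structure generator (exon/intron/intergenic
    elements with a piecewise-constant recombination map), a gamma
    distribution of fitness effects with additive, recessive, or h(s)
    dominance, exact ancestry-segment tracking alongside neutral marker
    mutations, parameter rescaling for compute-limited runs, and summary
    statistics: genetic load, Hudson/Bhatia F_ST, site frequency spectra,
    private/shared variant partitions, introgression deserts, and window-level
    correlations between introgressed ancestry, exon density, and
    recombination rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    IRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
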