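Package: msatclones
Title: Clonal Multilocus Genotype Analysis for Hybrid Parthenogens
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing diploid microsatellite genotype tables from
    clonally reproducing (parthenogenetic) lineages of hybrid origin and
    their bisexual parental species. Provides readers for wide and
    GenAlEx-style genotype tables, per-group allele frequency estimation,
    rarefied allelic richness, observed/expected heterozygosity and clonal
    genotype diversity summaries, Bruvo distances with minimum spanning
    networks and neighbor-joining trees, enumeration of single- and
    multi-locus genotypes shared between species, a probability model for
    the independent coincidence of multilocus genotypes under hybrid origin
    (with an allelic-conversion mode for homozygous loci), and a forward
    simulator of hybrid origin, clonal propagation, stepwise mutation, loss
    of heterozygosity and backcrossing with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
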