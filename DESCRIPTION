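Package: repliconsim
Title: Stochastic Simulation of Domino-Like DNA Replication and Nuclear
    Chromatin Folding
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven (kinetic Monte Carlo) simulation of whole-genome
    DNA replication in human cells, driven by stochastic spontaneous origin
    firing in open chromatin and domino-like induced firing near active
    replication forks, with a diffusible limiting factor capping the number
    of simultaneously active forks.  Genomes are modelled as chromosomes
    tiled by euchromatin, facultative and constitutive heterochromatin
    zones, parsed from UCSC cytoBand files or generated synthetically.
    Companion modules provide a random-loop bead-spring polymer model of
    chromatin folding inside an ellipsoidal nucleus sampled by Metropolis
    Monte Carlo, in-silico fluorescence microscopy rendering of replication
    foci, and analysis of inter-origin distances, one-dimensional fork
    clusters and replication-timing profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    tiff,
    png,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
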