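Package: dirmig
Title: Directional Genetic Differentiation and Relative Migration Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates directional components of genetic differentiation
    between pairs of populations from codominant allele frequency data.
    For every ordered pair of populations a hypothetical pool of migrants
    is built from the normalized geometric means of the two allele
    frequency vectors; Nei's Gst or Jost's D between each population and
    the pool yields an asymmetric differentiation matrix, which is
    transformed into directional relative migration under island-model
    assumptions. Significant asymmetries are detected by bootstrapping
    individuals within populations and testing for non-overlapping
    percentile confidence intervals. Includes a GENEPOP reader/writer, a
    structured-coalescent simulator of stepwise-mutation microsatellites
    for power studies under known gene-flow regimes, and export of
    gene-flow networks as edge lists, GraphML, or DOT.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    grDevices,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
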