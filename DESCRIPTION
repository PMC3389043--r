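Package: planktondiv
Title: Microplankton Diversity from Tagged 18S Amplicons and Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable analysis pipeline for coastal microplankton bloom
    surveys combining tag pyrosequencing of the 18S rDNA V2-V3 region with
    inverted-microscopy counts. Covers demultiplexing of 454-style tagged
    amplicon reads, lowest-common-ancestor taxonomic binning with bit-score
    filters, greedy centroid OTU clustering at a fixed identity threshold,
    rarefaction and richness/heterogeneity indices (Chao1, Shannon, Margalef,
    Simpson), a normalized between-date relative-change statistic,
    neighbor-joining phylogenetics under the Kimura two-parameter model with
    bootstrap supports, and conversion of microscopy counts and cell
    dimensions into carbon biomass stocks via geometric biovolumes and
    group-specific allometries. A seeded synthetic-data generator produces
    reference databases, bloom-structured communities, error-laden tagged
    reads, and microscopy tables so that the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
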