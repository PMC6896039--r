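Package: wrkyfam
Title: Survey Tools for Plant WRKY Transcription-Factor Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of the computational stages of a
    WRKY gene-family survey in Prunus mume: detection of WRKY domains by a
    heptapeptide scan paired with zinc-finger spacing grammars (C2H2 and
    C2HC types), rule-based and phylogenetic classification into groups
    I/II/III and subgroups IIa-e using a neighbour-joining tree with
    bootstrap support, tandem-repeat and gene-cluster calling from genomic
    coordinates, simplified collinearity-based segmental-duplication
    detection, exon/intron structure inference with R-type and V-type
    domain-intron classification, and expression analysis (RPKM, heatmap
    normalisation, fold-change candidate filtering, hierarchical
    clustering, and 2^-ddCt relative quantification of qPCR data). Ships
    the curated 58-gene family table as a fixture and seeded synthetic-data
    generators with planted ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    rtracklayer,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
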