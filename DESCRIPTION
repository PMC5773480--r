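Package: sceG4
Title: Mapping Sister Chromatid Exchanges onto G-Quadruplex Motifs from
    Strand-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for locating sister chromatid exchanges (SCEs)
    in strand-resolved single-cell sequencing (Strand-seq) libraries and
    testing whether they are enriched at G-quadruplex (G4) motifs and other
    genomic features. Provides template-strand state segmentation and SCE
    calling from directional reads, canonical G4 and control motif scanning,
    a circular-shift permutation test in assembly-gap-excluded coordinates,
    recurrent-breakpoint hotspot statistics, haplotype-resolved SCE/G4
    concordance testing, copy-neutral loss-of-heterozygosity calling, and a
    synthetic Strand-seq data generator with ground truth so that every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    IRanges,
    S4Vectors,
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
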