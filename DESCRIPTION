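Package: gutcohort
Title: Gut Microbiome Cohort Analysis: Sketch Similarity, Gene Screening,
    Core Taxa and Community Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for shotgun-metagenomic cohort studies of the
    human gut microbiome. Implements a repeated bottom-k 31-mer sketch
    genetic-similarity statistic between samples; presence calling of
    virulence factors, antibiotic-resistance genes and disease-related
    species from read alignments under identity and merged-coverage
    thresholds; core-taxon, diversity and enterotype summaries of
    relative-abundance tables; Bray-Curtis dissimilarity with PERMANOVA,
    principal-coordinate ordination, within/between group contrasts and
    longitudinal stability classification; and a synthetic cohort generator
    emulating a multi-region, multi-location design with a longitudinal arm,
    so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    Rcpp,
    IRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
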