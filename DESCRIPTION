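Package: pantrio
Title: Pan-Genome Base Classification for Trios of Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies every base of three related genome assemblies into the
    seven sectors of a three-way Venn diagram (core, pairwise-shared and
    genome-specific content) from whole-genome alignments, and validates the
    genome-specific calls with canonical k-mer coverage computed from
    unassembled sequencing reads. Includes an anchor-based whole-genome
    aligner (maximal unique match seeding, gap-bounded clustering, banded
    extension, one-to-one filtering, structural difference summaries), a
    canonical 21-mer counting and coverage-profiling engine with
    presence/absence calling for individual loci, exact interval set algebra
    on genome annotations, assembly summary statistics, and a synthetic
    genome-trio simulator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
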