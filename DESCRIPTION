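Package: polyTE
Title: Genome-Wide Translational Efficiency Analysis of Polysome Profiling Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the classic polysome-profiling measure of translational
    efficiency (TE): the ratio of a transcript's abundance in polysomal RNA to
    its abundance in total RNA, assayed on expression arrays. Implements the
    full analysis chain for a two-condition (wild-type versus mutant) design
    with biological and technical replicates: quantile normalization and
    median-polish (RMA-style) summarization of probe-level intensities,
    per-project and pooled TE computation, MA-plot variance diagnostics of the
    genome-wide narrowing of TE ranges, ordinary least-squares TE regression,
    threshold tabulation, ratio-plus-t-test gene classification, structural
    feature association (5'UTR/ORF/3'UTR length, upstream ORFs, essentiality,
    functional-category enrichment by Fisher's exact test), ribosome-density
    cross-referencing, and fraction-weighted 2^-ddCt quantification of qPCR
    polysome distributions. A synthetic-data generator with known ground truth
    emulates the study design so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
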