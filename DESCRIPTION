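Package: genehoods
Title: Scoring Co-Expressed, Syntenically Conserved Gene Neighborhoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores every candidate neighborhood of consecutive genes along a
    genome, across all requested window sizes simultaneously, by combining the
    average pairwise Spearman correlation of member expression profiles (ANC),
    an empirical p-value from a position-preserving permutation null, and the
    fraction of comparison species in which the neighborhood span lies within a
    single unbroken syntenic block (SS), into a Total Neighborhood Score
    (TNS = SS x ANC when p <= alpha, else 0). Includes readers for BED6/GFF3
    gene locations, expression and detection-call tables, and syntenic-block
    tables; a simplified marker-anchor block builder; per-gene annotations
    (Tau tissue specificity, adjacent-pair orientation classes, BLAST-based
    duplicate flags); report, bedGraph custom-track and TNS-matrix writers;
    and a truth-labelled synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    rtracklayer,
    GenomicRanges,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
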