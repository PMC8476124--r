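Package: derepressr
Title: miRNA Target De-Repression Scoring from Small-RNA and RNA-Seq Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies mature miRNAs from precursor-space small-RNA
    alignments with an end-window rule, aggregates counts to seed families,
    and scores per-family de-repression of predicted targets as a z-score of
    the mean log2-fold change against the transcriptome background, with
    cumulative-distribution (Kolmogorov-Smirnov) target-versus-background
    comparisons and bubble-plot summaries. Includes a synthetic-data
    generator (negative-binomial counts with abundance-proportional target
    de-repression, and small-RNA reads with jittered 5'/3' ends) so the full
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    ggplot2,
    jsonlite,
    methods,
    rlang,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
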