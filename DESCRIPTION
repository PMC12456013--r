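Package: txarch
Title: Bacterial Transcriptome Architecture from End-Enriched RNA-Seq Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the transcriptome architecture of a bacterial genome from
    stranded per-position sequencing tracks: calls transcription start sites
    (TSS) from differential RNA-seq (TEX+/TEX-) 5'-end counts, transcript
    3'-end positions (TEP) from Term-seq, classifies sites relative to a gene
    annotation (primary/secondary/internal/antisense/intergenic and
    cis-regulatory 3' ends), assembles coverage-supported transcription units
    and clusters, and models sigma-factor promoters as bipartite position
    weight matrices with spacer priors, exact score p-values, and a Gibbs
    sampler for de novo motif discovery. A seeded synthetic-data generator
    plants a full architecture (promoters, UTRs, RBS, intrinsic terminators,
    replicate and background noise) so every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    readr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
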