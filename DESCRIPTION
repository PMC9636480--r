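Package: nanodamr
Title: DamID-Seq and NanoDam Analysis from Reads to Reproducible Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained toolkit for Targeted DamID and NanoDam
    sequencing data: tiles a genome into GATC-delimited fragments, trims
    and length-filters DamID reads, aligns them on toy genomes or ingests
    SAM, accumulates extended-read fragment and bin counts, builds
    quantile-normalized log2 Dam-fusion/Dam-only binding tracks and
    CATaDa-style accessibility tracks, calls broad peaks with a Poisson
    local-lambda model, derives FDR-threshold consensus and reproducible
    peak sets across all pairwise fusion-versus-control comparisons, and
    provides library quality analyses (genome-wide correlation, library
    complexity, fingerprint, and signal-enrichment profiles) together
    with a sequencing pooling calculator and a seeded NanoDam read
    simulator with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    limma,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
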