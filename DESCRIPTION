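Package: exlnc
Title: Exercise-Responsive lncRNA Analysis with Chromatin Accessibility Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising long non-coding RNA (lncRNA) responses to
    endurance exercise training in a multi-tissue, two-sex, multi-timepoint
    design. Builds differential lncRNA sets from per-contrast effect tables
    (expression gate, raw-p and FDR schemes), combines sex-specific p-values by
    Fisher's sum-of-logs with Benjamini-Hochberg control within tissue strata,
    constructs a master ATAC-seq peak list (summit trimming, merging, count
    filtering), links lncRNAs to training-responsive peaks within a genomic
    window, correlates their log2 fold-change trajectories, and scores
    lncRNA-peak-gene triads by trajectory correlation weighted by proximity of
    the peak summit to the nearest protein-coding transcription start site.
    Includes sequence-level characterisation (GC content, small open reading
    frame discovery, microprotein search-database construction, group tests)
    and a seeded synthetic-data generator with ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
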