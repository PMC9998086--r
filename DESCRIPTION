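Package: eRNAscout
Title: Discovery of eRNA-Defined Enhancers from Cohort RNA-Seq and Open Chromatin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects enhancer RNA (eRNA)-producing regulatory regions from
    cohort total RNA-seq combined with ATAC-seq open-chromatin maps. Builds a
    truncated genome by excluding gene bodies with strand-aware promoter and
    termination flanks, merges per-sample peak sets into a union peak set,
    quantifies stranded fragments in candidate regions with count and
    fragments-per-million filters, scores transcriptional bidirectionality,
    tests two-cohort differential eRNA transcription with a negative-binomial
    Wald test and Benjamini-Hochberg correction, links eRNAs to target genes
    by nearest-gene and windowed expression correlation, stratifies genes by
    net enhancer change, classifies samples by correlation-based hierarchical
    clustering, and derives a Cox risk-score survival signature. Includes a
    seeded synthetic-data generator with planted ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
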