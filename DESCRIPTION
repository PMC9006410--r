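Package: lncScout
Title: Discovery and Functional Profiling of Long Non-Coding RNAs from
    Assembled Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for identifying novel long non-coding RNAs (lncRNAs)
    from assembled transcript models and profiling their regulatory
    potential. Assembled transcripts are compared against a reference
    annotation with gffcompare-style class codes and filtered for
    non-coding candidates; coding potential is scored with a CPAT-style
    logistic model over ORF, Fickett TESTCODE and hexamer-bias features;
    differential expression between two biological states is tested with a
    negative-binomial Wald model; co-regulated lncRNA:mRNA pairs are called
    from per-group Spearman correlation; and RNA:DNA:DNA triplex target
    sites are predicted under Hoogsteen base-pairing constraints. A seeded
    synthetic-data generator emulates the statistical structure of a
    two-state brain RNA-seq study and provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, DifferentialExpression,
    Sequencing, Annotation
RoxygenNote: 7.3.3
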