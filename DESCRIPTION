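Package: ribosec
Title: Ribosome Profiling Quantification of Selenocysteine UGA Readthrough
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for measuring the effect of dietary selenium on
    selenoprotein mRNA abundance and UGA-selenocysteine recoding from ribosome
    profiling and RNA-Seq libraries aligned in transcript space. Provides
    transcriptome loading and codon-window definition around UGA-Sec codons,
    a ground-truth footprint/RNA-fragment simulator, adapter trimming, rRNA
    depletion and unique two-mismatch alignment, metagene and triplet-phasing
    QC with A-site offset inference, windowed RPKM quantification with
    propagation-of-error fold changes, a 3'/5' RPKM readthrough estimator,
    and count-based differential expression (CPM filtering, TMM
    normalization, negative-binomial exact tests, BH FDR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    Rsamtools,
    jsonlite,
    optparse
Config/testthat/edition: 3
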