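Package: dmlpipe
Title: Paired Differential Methylation Analysis for 450K-Style Beta Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of Infinium 450K-style DNA methylation data
    for paired designs such as mesenchymal stem cell (MSC) chondrogenesis.
    Provides probe quality-control filtering, beta/M-value transformation,
    a paired empirical-Bayes moderated test for differentially methylated
    loci (DMLs) with Benjamini-Hochberg correction and a delta-beta effect
    filter, gap-based merging of DMLs into differentially methylated regions
    (DMRs), CpG-island/shore/shelf and chromHMM 15-state annotation with a
    five-category functional collapse, feature and chromatin-state enrichment,
    integration with gene expression changes, cross-tissue quantile
    normalisation with tissue-specific hypomethylation marker calling, and
    hypergeometric overlap testing between DML sets. A synthetic-data module
    generates manifests, paired beta matrices, tissue panels, expression
    tables and disease DML sets with planted ground truth so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
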