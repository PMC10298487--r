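Package: circkit
Title: Characterization and Enrichment Analysis of Circular RNA Catalogs
Version: 0.1.0
Authors@R:
    person("circkit", "maintainers", email = "maintainers@circkit.dev", role = c("aut", "cre"))
Description: Downstream analysis of back-splice-junction (circular RNA) calls
    against a gene annotation: host-gene assignment, spliced-length estimation,
    novel-versus-annotated classification against a known-circRNA database,
    catalog summaries, genome-distribution statistics, circular-versus-linear
    abundance comparison, RNA-seq/qPCR concordance by Spearman correlation with
    exact small-sample p-values, and a chi-squared overrepresentation test of
    upregulated circRNAs in host genes with a low genomic-length to exon-count
    ratio. Includes a seeded synthetic-data generator that emits complete,
    internally consistent input bundles (GTF, junction calls, linear
    quantification, known database, differential-expression tables, qPCR,
    microRNA target lists) with recoverable ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
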