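Package: cnvpool
Title: Multi-Caller Copy Number Variant Pooling and Consensus CNVR Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates copy number variant (CNV) calls from multiple
    structural-variant callers into population-level copy number variation
    regions (CNVRs). Provides reciprocal-overlap deduplication of pooled call
    sets, per-tool CNVR assembly with call-density trimming, two-or-more-tool
    consensus regions, breed-sharing and region-completeness filters,
    region-exclusive CNVR extraction, population structure from binary CNV
    presence/absence matrices (classical multidimensional scaling and
    neighbour-joining trees), gene/exon/QTL overlap with one-sided Fisher
    enrichment against a full QTL background, local gene-set
    over-representation, delta-delta-Ct relative copy number estimation from
    qPCR triplicates, and a fully seeded synthetic-data generator that
    emulates a multi-breed resequencing cohort for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    data.table,
    fgsea,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
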