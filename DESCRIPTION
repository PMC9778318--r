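Package: triosnp
Title: Trio-Based SNP Transmission Analysis and De Novo Mutation Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of parent-offspring trio variant calls with divergent
    parental genomes (e.g. a horse x donkey -> mule hybrid trio): hard-filter
    cascade on site quality annotations, SNP-cluster and region masking,
    two-method inheritance-state classification (Mendelian, Mendelian
    inheritance error with parental origin, de novo), read-support retention
    filters, per-genome heterozygosity and Ti/Tv summaries, per-site
    per-generation de novo mutation rate estimation, genomic region
    annotation against gene models with a 5 kb intergenic gene-assignment
    rule, and hypergeometric gene-set enrichment. Includes a seeded synthetic
    trio generator with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
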