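Package: uibscreen
Title: Classification and Screening of Intergenic-Breakpoint Gene Fusions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of DNA structural-variant fusions with
    matched expression data. Classifies fusion junctions by breakpoint
    annotation (gene-gene, gene-intergenic, intergenic-intergenic),
    predicts chimeric mRNAs arising from gene-intergenic fusions under a
    first-exon-skipping splicing model, and detects recurrent fusions with
    upstream or downstream intergenic breakpoints (UIB/DIB) that upregulate
    a target gene, using a distance-ordered split-search rank-sum screen
    with expression fold-change and copy-number filters. Includes a seeded
    synthetic-cohort simulator (annotation, SV call sets, expression,
    copy-number scores, junction evidence) with a ground-truth manifest so
    the full pipeline is testable without access to protected data.
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
    rtracklayer,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
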