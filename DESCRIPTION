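Package: colonyexpr
Title: Factorial Classification of Yeast Colony RNA-Seq Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-gene spatiotemporal and genotype expression classification
    for yeast colony RNA-seq. Implements trimmed-mean-of-M-values (TMM)
    library normalization with prior-damped log2 counts-per-million, per-gene
    two-factor ANOVA under additive (type II) and interaction (type III)
    models with Holm familywise correction, permutation-based empirical
    false-discovery rates, a variance/significance/r-squared partition
    cascade, factor-isolated hierarchical clustering with template-correlation
    pattern classification, Fisher exact cluster-overlap statistics, and a
    negative-binomial factorial count simulator with truth tables for
    recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    edgeR,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
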