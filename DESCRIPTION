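Package: migmod
Title: Co-Expression Modules and Rare-Variant Burden in Migraine Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated systems-genetics pipeline that discovers gene
    co-expression modules from expression data using a resampled consensus
    topological-overlap network with adaptive dendrogram branch pruning,
    validates modules by permutation, calls rare functional variants that
    segregate with disease in multi-generation pedigrees under a dominant
    model with a penetrance bound, tests each module for an excess of
    mutated genes with a one-tailed Fisher exact test and Bonferroni
    correction, replicates candidate modules in independent case and
    control cohorts, and annotates modules by expression-weighted
    cell-type enrichment and binomial pathway over-representation.
    Includes synthetic-data generators with known ground truth for
    expression matrices, pedigrees, variant tables and cell-type
    specificity, so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    vcfR,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
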