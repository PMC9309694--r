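Package: spongenet
Title: Competing Endogenous RNA Network Inference from Two-Group RNA-Seq Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers lncRNA-miRNA-mRNA competing-endogenous-RNA (ceRNA)
    networks from two-group count data, as used in transcriptome studies of
    age-related erectile dysfunction in geriatric rats. Provides TMM
    normalization and a negative-binomial exact conditional test for
    differential expression, Spearman/Pearson co-expression screening of
    miRNA-target and lncRNA-mRNA pairs, a hypergeometric shared-sponge
    test, tripartite network assembly with SIF/GraphML export, gene-set
    over-representation analysis, a raw-read quality filter, ICP/MAP
    phenotype grouping, 2^-ddCt qPCR fold changes, and a synthetic-data
    generator with planted ceRNA ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    igraph,
    jsonlite,
    Biostrings,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
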