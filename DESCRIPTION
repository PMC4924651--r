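Package: orthokinetics
Title: Cross-Species Comparison of Gene Expression Time-Course Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing replicated RNA-seq expression time courses
    between orthologous genes of two species, built around a Gaussian-process
    Bayes-factor test for conserved, possibly time-shifted, expression
    kinetics. Includes expression filtering, fold-change ranking and
    cross-species concordance of differentially expressed genes, joint
    k-means profile clustering, hypergeometric enrichment of disease lead-SNP
    windows and functional classes, permutation testing of chromosomal gene
    co-localization, lncRNA biotype and co-expression analyses, a synthetic
    data generator with planted ground truth for every input, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
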