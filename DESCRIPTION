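Package: methcrossover
Title: Cross-Contrast Differential Methylation Analysis for Whole-Blood RRBS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for reduced-representation bisulfite
    sequencing (RRBS) cross-contrast analysis of whole-blood DNA
    methylation. Calls differentially methylated CpGs by per-site
    binomial logistic regression with an age covariate, segments them
    into regions using a distance-mixture cutoff and signed Stouffer
    combination, intersects two case-control contrasts, classifies
    direction concordance and tests the association by chi-square,
    profiles genomic context (promoter/exon/intron/intergenic, CpG
    island/shore/open sea), selects candidate regions nonparametrically
    (Kruskal-Wallis plus exact Mann-Whitney U), scores gene-set
    enrichment with the EASE modified Fisher exact test, and verifies
    expression consequences via TMM-normalized row-centered log-CPM.
    Ships a synthetic-data generator (beta-binomial methylation counts
    with planted differentially methylated regions, annotations,
    negative-binomial expression counts) so every stage is exercisable
    without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    mclust,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
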