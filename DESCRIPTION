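Package: pcdtriage
Title: Pathogenicity Triage of Primary Ciliary Dyskinesia Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-silico triage of candidate variants in genes linked
    to primary ciliary dyskinesia (PCD). Consolidates five pathogenicity
    predictors (MetaLR, MetaSVM, scaled CADD, REVEL, Condel) per variant from
    an annotated cohort table, clusters variants into pathogenic / uncertain /
    benign classes by k-means in a five-score view and a REVEL-by-Condel
    scatter view, embeds the score matrix by classical multidimensional
    scaling, scores cross-species residue conservation with a gap-penalised
    Jensen-Shannon divergence, compares clusters with the tie-corrected
    Kruskal-Wallis H test, and models autosomal-recessive disease risk for
    couples sharing heterozygous variants with a binomial model. A transcribed
    112-variant PCD cohort table is bundled, and simulators for score tables
    and protein alignments support end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
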