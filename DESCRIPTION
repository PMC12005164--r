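Package: imprintr
Title: Allele-Specific Imprinting Dynamics in Triploid Endosperm from
    Reciprocal Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calling genomic imprinting from allele-resolved
    RNA-seq of reciprocal crosses in triploid endosperm. Implements reads-per-million
    normalization, the reciprocal expression ratio (RER) statistic with its 2:1
    maternal:paternal dosage null, a negative-binomial fold-change-threshold Wald
    test with Benjamini-Hochberg FDR control for maternal-vs-paternal and
    developmental contrasts, maternally/paternally expressed gene (MEG/PEG) and
    parental-bias status calling across time points, a four-group
    temporal-consistency classification, syntelog-based conservation scoring across
    genotypes, max-normalized k-means clustering of developmental trajectories with
    reciprocal-direction transfer, endosperm-preference classification against a
    tissue atlas, and a seeded negative-binomial simulator of reciprocal-cross
    experiments with known per-gene imprinting truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
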