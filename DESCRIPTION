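Package: binqtl
Title: Bin-Based Linkage Mapping and QTL Analysis for F1 Pseudo-Testcross Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genetic map construction and quantitative trait locus
    (QTL) analysis in F1 progenies of two outbred parents, built around a
    bin-based correction of genotyping errors in dense resequencing-derived
    SNP data. Includes marker filtering and AHB recoding with a
    pseudo-testcross split into 1:1 and 1:2:1 datasets, automated phasing,
    detection of recombination breakpoints under a double-recombination
    acceptance rule, construction of one-marker-per-bin genotype matrices,
    Kosambi genetic maps with identity-by-descent gap accounting,
    Haley-Knott interval mapping with permutation thresholds and gene-action
    classification, a CIELAB-based fruit color scoring model with
    cross-validation, trait statistics including broad-sense heritability,
    and a synthetic-data generator that emulates the full study design for
    testing.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
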