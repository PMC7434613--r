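Package: paravar
Title: Paralog-Aware Conservation Analysis of Gene-Family Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps missense variants from the members of a gene family (such as
    the nine voltage-gated sodium channel alpha-subunits) onto the shared
    column coordinates of a family multiple protein alignment, scores paralog
    conservation as a per-column z-score, classifies variants with a
    six-tool in-silico consensus rule and a documented ACMG-style evidence
    engine gated on a gnomAD allele-frequency threshold, and tests whether
    case variants are enriched at conserved and transmembrane positions
    relative to population controls using Welch t, Fisher exact, and seeded
    permutation tests. Ships a seeded synthetic-data generator emulating a
    paralog family with mixed-conservation columns so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
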