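Package: symbiopleio
Title: Genomic Signatures of Cooperation and Conflict in Legume-Rhizobium Symbiosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for dissecting fitness alignment and conflict
    between a legume host and its rhizobium symbiont. Computes rack-corrected
    estimated marginal strain means for single-strain fitness proxies,
    reconstructs strain frequencies from pooled nodule sequencing to obtain a
    select-and-resequence relative-fitness proxy, runs kinship-corrected
    linear-mixed-model genome-wide association for every trait-by-host
    combination, sets permutation-based significance thresholds, classifies
    pleiotropic variants as concordant (fitness alignment) or discordant
    (fitness conflict), and compares diversity and neutrality statistics
    (pi, Watterson's theta, Tajima's D, Fu and Li's D* and F*) between
    pleiotropy gene categories. Ships a synthetic-data generator with a
    ground-truth ledger so the full chain is testable without external data.
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
    jsonlite,
    yaml,
    generics,
    emmeans,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    ape,
    optparse
Config/testthat/edition: 3
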