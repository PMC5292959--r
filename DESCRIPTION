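Package: morphosplit
Title: Morphotype Split-Marker Scans and Copy-Number Analysis for
    Structured Crop Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting markers and genomic regions that separate
    morphotype pools in structured crop diversity panels, with Brassica
    napus winter/spring/semi-winter/swede panels as the motivating case.
    Implements merging and quality filtering of SNP-array and
    sequencing-derived genotype calls, population structure via the
    modified Rogers distance with principal coordinate analysis and
    k-means, a two-stage chi-square split-marker scan with pool-polarized
    alleles and log-space p-values, diagnostic haplotype classification
    across split regions, read-depth based copy-number calling with
    homoeologous-exchange flagging, candidate gene reporting near split
    regions, and a seeded synthetic-panel generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
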