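Package: msyscan
Title: Discovery and Dating of Male-Specific Y Regions from Sexed Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for discovering cryptic sex chromosomes
    from sexed sequencing data. Implements male/female transcript subtraction
    with canonical k-mer filtering and unitig assembly, genomic coverage-ratio
    scanning for half-coverage (hemizygous) regions, XY gametolog pairing by
    global alignment, Nei-Gojobori (1986) synonymous-substitution dating of the
    XY split with codon-bootstrap confidence intervals, climate-based outlier
    classification of temperature- versus genotype-dependent sex determination,
    and Fisher exact enrichment of Y-linked markers in the detected region.
    A seeded synthetic-data generator plants a male-specific Y region of known
    age and provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
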