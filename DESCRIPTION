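Package: coldscreen
Title: Temperature-Differential Genetic Interaction Screen Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for arrayed genetic-interaction screens run at
    two growth temperatures, as used to map cold-specific suppressors and
    synthetic-sick interactors of fission-yeast telomere mutants. Implements
    per-plate median normalization of colony sizes (NG), the normalized growth
    ratio cold-specificity statistic (NGR = NG at 19C / NG at 30C), outlier
    hit calling by the top-25th-percentile and 2-SD methods, comparative
    classification across parallel query screens (query-specific interactors,
    cold-sensitivity suppressors, and mitotic-function reverters), and
    hypergeometric gene-ontology over-representation with Benjamini-Hochberg
    correction. Ships a synthetic plate-data generator emulating the screen
    design (multiplicative plate effects, log-normal colony noise, dropout,
    technical triplicates, planted interactions) so the whole pipeline is
    testable end to end without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
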