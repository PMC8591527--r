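Package: rbalance
Title: Resource Balance Analysis of Microbial Proteome Allocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and solves resource balance analysis (RBA) growth models
    that couple metabolic flux to the enzyme and macromolecular-machinery
    concentrations needed to sustain it under a finite, compartmentalized
    protein budget.  Includes apparent catalytic rate (k_app) calibration
    from flux sampling and proteomics, enzyme utilization scoring against
    minimal predicted abundance, a transposon insertion-index gene
    essentiality classifier based on a two-component gamma mixture, a
    barcoded-mutant (BarSeq) gene fitness scorer, chemostat physiology
    helpers, and synthetic-data generators with known ground truth for
    validating every analysis stage.
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
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
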