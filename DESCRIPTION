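Package: eimbiome
Title: Fecal Microbiota Analysis for IBD Extraintestinal Manifestations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end 16S rRNA amplicon sequence variant (ASV) analysis
    pipeline for comparing the fecal microbiota of inflammatory bowel disease
    (IBD) patients with and without extraintestinal manifestations (EIMs).
    Implements negative-control decontamination and abundance/prevalence
    filtering of ASV count tables, alpha diversity, unweighted and weighted
    UniFrac with PERMANOVA, a multi-model differential-abundance procedure
    (gaussian, Poisson, negative binomial and zero-inflated negative binomial
    candidates selected by AIC), SparCC compositional correlation networks
    with threshold-defined co-association modules, logistic module-phenotype
    association, cohort enrollment bookkeeping with exact contingency tests,
    and a synthetic community generator with planted ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
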