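Package: ligasetrap
Title: Substrate Discovery and Validation Analysis for Ubiquitin Ligase
    Trapping IP-MS Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for ligase-trapping affinity-purification
    mass-spectrometry (AP-MS) screens of ubiquitin-ligase substrates.
    Calls candidate substrates from bait versus negative-control spectral
    count tables using a replicated presence/absence rule with family
    exclusion groups, scores bait enrichment and normalized spectral
    abundance factors (NSAF), scans candidate protein sequences for
    relaxed beta-TRCP phosphodegrons (DpSGX(1-4)pS with acidic
    substitutions tolerated), fits first-order decay kinetics to
    cycloheximide-chase densitometry to estimate half-lives and classify
    stabilization, and tallies discovery/validation outcomes. A seeded
    synthetic-data generator produces IP-MS count tables, degron-bearing
    sequences, and decay timecourses with known ground truth so every
    stage is testable without external data.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
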