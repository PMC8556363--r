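Package: driverdelta
Title: Burden-Adjusted Differential Prevalence of Somatic Driver Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes somatic mutation calls (copy-number segments, coding
    and non-coding single nucleotide variants, structural variants) across
    tumor cohorts into a per-sample by per-mutation-type matrix with
    class-specific denominators, estimates mutation prevalence with Wald
    confidence intervals, and tests each driver mutation for enrichment in
    metastatic versus localized disease beyond what per-sample mutational
    burden predicts, using a Monte-Carlo simulated binomial null with
    empirical p-values and Benjamini-Hochberg correction. Candidate
    prognostic mutations are filtered by localized prevalence and screened
    against survival outcomes (Kaplan-Meier, log-rank, Cox proportional
    hazards, two-by-two odds ratios). A synthetic-cohort generator with
    planted enrichment effects and hazards makes every stage testable
    without external data.
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
    stringr,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    IRanges,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
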