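Package: bpadhere
Title: Adherence Analysis of Brand Versus Generic Oral Bisphosphonates from Dispensing Claims
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for comparing medication adherence between brand
    and generic oral bisphosphonate initiators using dispensing-claims tables.
    Implements new-user cohort selection with washout, exclusion and switcher
    rules; persistence as time to discontinuation under a refill-gap rule with
    hospitalization adjustment; implementation as the continuous
    multiple-interval measure of medication availability version 7 (CMA7) with
    supply carry-over and hospital coverage extension; stabilized inverse
    probability of treatment weighting with standardized-difference balance
    diagnostics; and weighted Fine-Gray (competing risk of death) and
    log-binomial effect models with robust variance. Includes a synthetic
    claims generator with exported ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    rlang,
    sandwich,
    stats,
    survival,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
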