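Package: crcstrat
Title: Sex-Stratified Colorectal Cancer Screening Microsimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual patient-level microsimulation of colorectal cancer
    natural history and fecal immunochemical test (FIT) screening, built to
    evaluate sex-stratified screening start ages under a fixed-resource
    (equal mean screening episodes) constraint. Provides a nine-state
    adenoma-carcinoma natural-history engine with calibration of transition
    parameters to age- and sex-specific incidence and prevalence targets, a
    screening pathway with colonoscopy follow-up, polypectomy, complications
    and post-polypectomy surveillance, strategy constructors enforcing
    episode parity, a lifetime discounted cost and QALY engine producing
    ICER and net monetary benefit with per-100,000 clinical and resource
    outcomes, probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, and a synthetic-data module that emulates the
    structure of English survey, registry and tariff inputs so the whole
    pipeline is testable without external data.
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
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
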