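Package: dmardmon
Title: DMARD Safety-Monitoring Indicators from Primary-Care EHR Events
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for auditing adherence to disease-modifying
    antirheumatic drug (DMARD) safety monitoring in primary-care
    electronic health records. Builds monthly missed-monitoring
    indicators for azathioprine, leflunomide and methotrexate from
    prescription-window cohorts with a rolling three-month test
    lookback and disclosure-control rounding to the nearest 5;
    summarises practice-level variation as deciles; and tests
    period-to-period changes (two-proportion z) and subgroup
    heterogeneity of changes (Cochran's Q). Includes a seeded
    synthetic EHR generator with repeat prescribing, cyclic
    monitoring tests, practice random effects, subgroup effects and
    a configurable transient service disruption, so the whole
    pipeline runs without access to real patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    lubridate,
    ggplot2,
    readr,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
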