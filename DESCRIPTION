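Package: effidiff
Title: Efficiency Measurement, Inequality Decomposition and Grey
    Forecasting for Provincial Health Services
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for measuring and decomposing regional differences in
    the technical efficiency of health-service providers. Implements the
    slacks-based measure (SBM) of efficiency and its super-efficiency
    extension under variable or constant returns to scale, solved exactly
    as linear programs; generalized-entropy inequality indices with the
    Theil within/between-region decomposition and contribution shares;
    and the GM(1,1) grey model for forecasting short annual series such
    as an inequality-index trajectory. Ships the published provincial
    efficiency panel for Chinese community health services (2008-2016),
    the three-region province partition, and a synthetic-data generator
    with known frontier and known efficiency structure so that every
    pipeline stage can be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
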