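Package: webrds
Title: Web-Based Respondent-Driven Sampling: Coupon Tracking, Estimation
    and Recruitment Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for running and analysing web-based respondent-driven
    sampling (WebRDS) surveys of hidden populations. Implements a chained
    invitation-token (coupon) ledger with use budgets, administrative
    corrections and duplicate-response detection; reconstruction of the
    recruiter-to-recruit forest from token linkage with recruitment
    performance summaries; the RDS-II (Volz-Heckathorn) inverse-degree
    proportion estimator with Salganik-style chain-bootstrap confidence
    intervals; recruitment homophily and convergence/bottleneck
    diagnostics; and a recruitment simulator over synthetic assortative
    contact networks so the whole pipeline can be exercised without field
    data. Includes a deterministic benchmark forest reproducing the
    recruitment summary of a nationwide WebRDS survey of homecare workers,
    CSV dialects mirroring a LimeSurvey token/response export, a
    monitoring report generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
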