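Package: storeflux
Title: Longitudinal App-Store Dynamics: Half-Life Estimation, Screening and
    Marketplace Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing daily snapshot panels of app marketplace
    search results. Implements the shifted-cohort survival estimator for the
    "search result half-life" and "app half-life" of mobile apps (per-start-day
    cohort survival series, common-origin alignment, minimum-support
    averaging and 50% threshold crossing with censoring), removal-interval
    arithmetic, an effectiveness-claim keyword filter, dual-reviewer
    relevance adjudication, top/bottom subgroup analyses, and a seeded
    birth-death marketplace simulator (Poisson arrivals, class-specific
    removal hazards, popularity random walks, truncated top-K search
    rankings, rating accumulation, masked observation days) that provides
    panels with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
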