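Package: hinhcost
Title: Cost Analysis of a Hospital in the Nursing Home Program
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Health-economic cost analysis of an emergency-department-based
    Hospital in the Nursing Home (HiNH) outreach program for residential aged
    care facility (RACF) residents. Provides a synthetic generator for
    episode-level and monthly hospital-utilisation data with a 2x2 pre-post
    controlled structure, difference-in-differences Poisson and gamma
    log-link generalized linear models with marginally standardized adjusted
    means, a deterministic annual net-cost ledger combining program costs
    with utilisation cost differences, and a Monte Carlo probabilistic
    sensitivity analysis with rank-correlation contribution-to-variance
    attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
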