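Package: saltcost
Title: Attributable Healthcare Costs and Productivity Losses of Excess Dietary Salt
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative risk assessment pipeline estimating the direct
    healthcare costs (hospitalizations, consultations, medications) and
    human-capital productivity losses attributable to population salt intake
    above the WHO 5 g/day limit. Salt intake acts on cardiovascular disease
    through systolic blood pressure: a truncated-normal intake distribution is
    discretized into exposure bins, per-mmHg relative risks are rescaled to
    per-bin risks, combined into a population attributable risk (PAR) by sex
    and age group, and applied to national cost tables. Premature-mortality
    losses are monetized via years of potential productive life lost and the
    human-capital approach. Monte Carlo propagation of input uncertainty
    yields 95 percent uncertainty intervals. Ships a synthetic input generator
    parameterized like Costa Rica 2018.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
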