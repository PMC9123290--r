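Package: genderwork
Title: Sex and Gender Differences in Depressive Symptoms Among Older Workers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying sex and gender inequalities in depressive
    symptoms among older workers. Implements a six-item labour-market
    gender-role index (working hours, equivalized income, occupation
    segregation, education, informal caregiving, household chores), maximum
    likelihood tobit regression for a left-censored CES-D outcome, moderation
    tests of the differential vulnerability hypothesis, single-mediator causal
    mediation with bootstrap percentile confidence intervals for the
    differential exposure hypothesis, chained-equations multiple imputation
    with Rubin's rules pooling, and a seeded synthetic cohort generator that
    emulates a population-based sample of older workers so the whole pipeline
    can be exercised without access to restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
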