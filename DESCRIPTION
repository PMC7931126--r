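Package: oncoprev
Title: Microsimulation of Cancer Primary Prevention Policies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dynamic microsimulation of cancer-related health and economic
    outcomes under primary-prevention policies targeting diet, physical
    activity and alcohol. Generates a synthetic country (demography,
    risk-factor quantile distributions, baseline cancer epidemiology,
    treatment costs, alcohol price elasticities), evolves individual life
    histories with relative-risk-driven incidence of breast, colorectal,
    oesophageal and liver cancer, five-year case fatality with weighted
    death timing and remission, applies six policy interventions (menu and
    food labelling, mass media campaigns, workplace sedentary-behaviour
    programmes, an alcohol tax and minimum unit pricing), and compares
    paired counterfactual scenarios under common random numbers to report
    cancer cases avoided, healthcare expenditure savings and DALYs with
    replicate-based confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
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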