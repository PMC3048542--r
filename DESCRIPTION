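Package: aafhiv
Title: Alcohol-Attributable Fractions for HIV/AIDS Mortality via
    Antiretroviral Nonadherence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stepwise estimation of the fraction of HIV/AIDS deaths
    attributable to alcohol consumption acting through nonadherence to
    antiretroviral therapy.  Combines the adherence-attributable fraction
    of deaths (AdAF), the fraction of nonadherence attributable to current
    drinking (NAAAF), and the share of HIV/AIDS deaths occurring among
    people on treatment (PDT) into a single alcohol-attributable fraction
    AAF = AdAF * NAAAF * PDT, with closed-form delta-method (Taylor-series)
    variances and untruncated Wald-type 95% uncertainty intervals.
    Converts published odds ratios, risk ratios and hazard ratios with
    confidence intervals into the linear-scale variances the fraction
    arithmetic consumes, bundles 2005 regional input tables for the five
    Global Burden of Disease regions of Africa (antiretroviral coverage
    and prevalence of current drinkers by sex and age band), accepts
    user-supplied tables in documented CSV or JSON dialects, and validates
    every analytic variance against a Monte Carlo simulation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
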