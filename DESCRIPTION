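Package: psyvar
Title: Small-Area Variation Analysis of Psychotropic Dispensing in Children and Youth
Version: 0.1.0
Authors@R:
    person("psyvar", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for small-area variation analysis of psychotropic drug
    dispensing among children and youth: direct age- and sex-standardized
    dispensing rates per census division, classical variation statistics
    (extremal quotient, population-weighted coefficient of variation,
    systematic component of variation with interpretation bands),
    per-division chi-square tests against the provincial rate with
    multiple-comparison control, baseline descriptive comparisons with
    standardized differences and Spearman correlations, and log-link
    generalized estimating equations (quasi-Poisson or negative binomial
    variance, exchangeable or independent working correlation, cluster-robust
    sandwich covariance) for individual- and division-level correlates of
    dispensing. A synthetic cohort generator emulating a provincial
    population of 0-24 year olds makes every stage testable without access
    to restricted administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
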