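Package: previnc
Title: Age-Specific Incidence of Chronic Disease from Aggregated Prevalence
    via the Illness-Death Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates age- and sex-specific incidence rates of a chronic
    disease (the motivating application is diagnosed arterial hypertension in
    Germany) from aggregated, age-grouped prevalence proportions and all-cause
    mortality rates, using the illness-death model and its transport partial
    differential equation. Provides a Gaussian parametric incidence curve, a
    log-linear age-specific mortality rate ratio, a characteristics-based
    forward prevalence solver and the corresponding incidence inversion,
    non-linear least-squares parameter estimation with a fixed peak age, a
    perturbation bootstrap for confidence intervals on aggregated proportions,
    a Human Mortality Database style life-table reader with life-expectancy
    functionals, and a synthetic-data generator emulating claims-scale
    aggregated prevalence for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp
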