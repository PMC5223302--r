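Package: handrct
Title: Exposure-Adjusted Reanalysis of Cluster-Randomized Hand-Hygiene Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and reanalysing triplet-matched
    cluster-randomized hand-hygiene trials with weekly self-reported
    respiratory (RTI) and gastrointestinal (GTI) symptom and exposure
    diaries. Generates synthetic longitudinal person-week cohorts with
    person and cluster random intercepts, monthly seasonality and
    incomplete reporting; converts daily symptom diaries to
    weeks-with-symptoms endpoints and designated episodes; computes
    exposure-conditioned relative risks (ReR) and descriptive arm risk
    ratios (RRa); fits a Bayesian hierarchical log-link binomial
    regression by adaptive Metropolis-within-Gibbs MCMC; and derives
    posterior predictive margins of weekly prevalence, arm risk ratios
    with credible intervals, and posterior probabilities that a risk
    ratio is below one.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    coda,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmmTMB
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
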