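Package: marepain
Title: Postpartum Mare Pain Scale Scoring and Salivary Cortisol Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores the composite behavioural pain scale for postpartum
    mares: item-level scoring against a versioned instrument definition,
    skip-adjusted percentage normalisation, a 40-percent analgesia decision
    threshold, and serial trajectory monitoring.  Also provides the
    physiological validation pipeline that anchors the scale to salivary
    cortisol: technical-replicate quality control (absolute floor filter
    and a projection-based robust multivariate outlier screen), a Bayesian
    linear mixed model of cortisol on pain score with per-mare random
    intercepts and slopes fitted by MCMC, prior and posterior predictive
    checks, convergence diagnostics, leverage-point and default-prior
    sensitivity analyses, and a synthetic-cohort generator so the whole
    pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    jsonlite,
    MASS,
    rjags,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
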