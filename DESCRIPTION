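Package: subfunr
Title: Mechanistic Markov Model of Gene Duplicate Retention Under
    Subfunctionalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Continuous-time Markov chain (phase-type) model for the fate of
    a pair of gene duplicates evolving under regulatory subfunctionalization,
    with competing absorption into subfunctionalization and pseudogenization.
    Provides exact transient distributions, absorption probabilities and
    moments, hazard and cause-specific hazard rates, the pseudogenization
    rate and its shape diagnostics (critical mutation-rate ratio, inflection
    points), a Poisson-duplication count likelihood for binned duplicate-pair
    data with maximum-likelihood fitting over the number of regulatory
    regions, profile-likelihood intervals and AIC comparison against Weibull
    and exponential survival baselines, plus an exact stochastic simulator
    used as an independent oracle and synthetic-data generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
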