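Package: tutakoke
Title: Hierarchical Bayesian Trend Models for Brant Brood Rearing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits Bayesian hierarchical mixed-effects trend models for
    long-term studies of black brant (Branta bernicla nigricans) brood
    rearing: a normal growth model for gosling mass with year-specific
    daily growth rates around a linear hyper-trend, binomial models for
    the aerial extent of Carex subspathacea grazing lawns from
    photographic point counts, and binomial models for scan-sampled
    behavioral time budgets. Provides a posterior-resampling regression
    for correlating annual estimates across models, a probability-of-
    direction (f) statistic, convergence diagnostics, a synthetic-data
    generator for parameter-recovery validation, and a reproducible
    pipeline over CSV inputs. The Gibbs and Metropolis-within-Gibbs
    sampler is implemented in the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rjags
Config/testthat/edition: 3
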