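Package: egug
Title: The Exponentiated Gumbel-G Family of Survival Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Density, distribution, quantile, hazard and random-variate
    functions for the exponentiated Gumbel-G (EGuG) family of lifetime
    distributions, obtained by passing a positive baseline distribution
    through an exponentiated-Gumbel transformer, together with its
    three-shape-parameter special case built on the Nadarajah-Haghighi
    baseline (EGuNH). Provides moments, inequality curves and
    quantile-based shape measures, actuarial risk measures (value at
    risk and expected shortfall), maximum-likelihood estimation with
    observed-information standard errors and likelihood-ratio tests,
    goodness-of-fit model comparison (AIC/BIC, Anderson-Darling,
    Cramer-von Mises, Kolmogorov-Smirnov), a Monte-Carlo study of
    estimator quality, and three classical survival/event datasets
    (earthquake waiting times, leukemia survival times, blood-cancer
    incidence counts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lhs,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
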