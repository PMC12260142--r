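Package: posdesign
Title: Decision-Theoretic Probability of Success and Sample Size for Clinical Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Planning tools for superiority trials analysed with a one-sided
    z-test on a normal (e.g. log odds ratio) summary. Computes the Bayes
    utility of the test under a design prior (the expected probability of
    choosing the true hypothesis, u-PoS) alongside three classical hybrid
    frequentist-Bayesian probability-of-success measures: the joint
    probability of a correct rejection, the expected power conditional on
    the alternative, and assurance (the marginal probability of rejection).
    Design priors include point-mass, normal, skew-normal, truncated-normal
    and two-component normal mixtures, with an optional inverse-gamma prior
    on the sampling variance. Measures are evaluated by deterministic
    quadrature, by Monte Carlo with common random numbers, or in closed form
    where available, and drive sample size determination with feasibility
    checks against the large-sample limits of each measure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
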