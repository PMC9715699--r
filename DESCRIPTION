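Package: streamlimits
Title: Upper Distribution Limits of Fish on Dendritic Stream Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage modelling of the upstream distribution limit of
    stream-dwelling fish. Stage one fits reach-level presence models
    (logistic regression or random forest) to occurrence labels propagated
    along a dendritic stream network from observed upper-limit points, using
    hydro-topographic covariates accumulated along the flow network (upstream
    channel length, drainage area, downstream channel slope, median-normalized
    elevation). Stage two collapses per-reach presence probabilities into a
    single upper-limit point per flow path with configurable network stopping
    rules, including a slope-threshold baseline. Includes nested spatial
    (block) cross-validation with the Matthews correlation coefficient,
    along-network mean absolute error between observed and predicted limit
    points, model-explanation utilities, and a seeded synthetic-hydrography
    generator so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ranger
Suggests:
    glmnet,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
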