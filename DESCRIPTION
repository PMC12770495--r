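Package: helpcb
Title: Cost-Benefit Models of Naturalistic Helping Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for cost-benefit models of
    everyday helping decisions. Generates synthetic scenario, rater, agent and
    trait data with known structure; applies survey quality-control and
    consensus aggregation with inter-rater reliability (ICC(A,k)); reduces
    motivation ratings to latent benefit/cost factors by exploratory factor
    analysis with parallel analysis; fits and compares seven softmax utility
    models of binary helping choices by maximum likelihood, with pseudo-R2,
    AIC/BIC, leave-one-out accuracy and parameter-recovery simulation; builds
    decision, motivation and semantic representational spaces and relates them
    with representational similarity analysis, RDM regressions and Welch and
    Games-Howell tests; and runs permutation and bootstrap individual
    difference statistics linking model parameters to trait scores.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lhs,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
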