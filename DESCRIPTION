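Package: imcor
Title: Bayesian Correlation Pipeline for TMS Movement-Imagery Ability Studies
Version: 0.1.0
Authors@R:
    person("BAS", "Lab Tools", email = "tools@example.org", role = c("aut", "cre"))
Description: Simulation, scoring and inference tools for studies relating
    corticospinal excitability during movement imagery to behavioural measures
    of imagery ability. Provides a synthetic cohort generator linked through a
    latent imagery-ability factor; constraint-based pseudo-randomized schedules
    for TMS sessions, hand-laterality judgement blocks and a chronometric
    radial Fitts task; quality control and derivation of motor-evoked-potential
    outcome measures (percentage MEP change and change in short-interval
    intracortical inhibition); scoring of the MIQ-RS questionnaire, Gamma-GLM
    Fitts-slope differences and hand-laterality reaction times; a from-scratch
    Bayesian Pearson/Spearman correlation engine (stretched symmetric beta
    prior, Savage-Dickey Bayes factors, probability of direction, ROPE and
    credible intervals); a sequential optional-stopping design with prior
    shrinkage; and closed-form and simulation-based sample-size and power
    calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
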