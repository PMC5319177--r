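Package: rxcover
Title: Day-Level ART Prescription Coverage and Mixed-Effects Evaluation of
    SMS Adherence Support
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating clinic-based adherence support programs
    from routinely collected pharmacy records. Converts antiretroviral
    therapy (ART) prescription histories into day-level prescription
    coverage under a carryover rule with a clinic cap, deduplication of
    re-recorded six-month prescriptions, and right-censoring at transfer
    out; builds an intention-to-treat cohort with exposure groups defined
    by mobile-phone availability; fits a patient-level random-intercept
    logistic model with a group-by-period interaction (via 'lme4') with
    stepwise backward elimination of candidate covariates; and translates
    the adjusted odds ratio of the program effect into days of prescription
    coverage gained per year. Includes a synthetic clinic-data generator
    (behavioral refill-process and model-faithful modes) for validation
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
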