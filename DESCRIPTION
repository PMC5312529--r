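Package: augctrial
Title: Simulation and Analysis of Augmented-Control Oncology Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design, simulation, and analysis machinery for randomized
    oncology trials whose primary analysis compares overall survival with a
    Bayesian augmented-control model: conjugate gamma posteriors for
    exponential hazards, power-prior borrowing from historical control
    data, the posterior probability of superiority decision rule, and
    Monte-Carlo operating characteristics (type I error, power).
    Companion analyses cover Kaplan-Meier estimation with one-sided
    log-rank sensitivity testing and Schoenfeld design power, exact
    Clopper-Pearson binomial endpoints (response and clinical benefit
    rates, duration of response, tumor-size and CA19-9 response),
    noncompartmental pharmacokinetics (AUC, lambda-z, clearance, Vss,
    exposure-target attainment), and safety tabulation with
    Fridericia-corrected QT change categories.  A synthetic patient-level
    trial generator (2:1 block randomization, exponential survival,
    two-compartment infusion pharmacokinetics, adverse-event and ECG
    records) makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
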