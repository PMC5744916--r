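Package: metminer
Title: Association Rule Mining and Pre-Emptive Policy Modelling for
    Medical Emergency Team Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing Medical Emergency Team (MET, rapid
    response team) call records: a validated two-table cohort data model
    with CSV readers and writers, a seeded synthetic-cohort generator and
    deterministic margin-matched fixture builders, statistically sound
    association rule mining (k-optimal search over antecedents of up to
    three items with productivity testing and Bonferroni familywise-error
    control), a classical two-group comparison and logistic-regression
    battery, an executable nurse-initiated intravenous-fluid decision rule
    for hypotension calls, and counterfactual evaluation of that rule on a
    held-out cohort (averted-call accounting and a prediction confusion
    matrix).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
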