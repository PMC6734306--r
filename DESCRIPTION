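Package: mmdiary
Title: Statistical Diagnosis of Menstrual Migraine from Daily Headache Diaries
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of daily headache diaries for diagnosing menstrually
    related migraine. Models migraine attacks as a two-state Markov chain
    with a per-day onset probability that may be elevated inside the 5-day
    perimenstrual window, and tests for that elevation with a one-sided
    hypergeometric exact test with mid-p correction applied to attack-onset
    days only (the "sMM" statistical criterion). Diaries are first trimmed:
    days on which an attack is ongoing, and the two days following each
    attack, are removed so that only days on which a new attack could start
    enter the test. Also provides the ICHD-style two-out-of-three window
    criterion, diary preprocessing (atypical-cycle removal, truncation,
    migraine-locked-day imputation), a seeded Markov-chain diary simulator,
    and ROC/AUC comparison of the two diagnostic criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr, optparse, yaml, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
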