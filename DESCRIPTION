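Package: weartrial
Title: Offline Engine for Wearable-Device Clinical Trial Management
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless, offline-testable engine for running multi-phase
    behavioral-trial data acquisition: participant registry and event-sourced
    study tracking, adaptive questionnaires with branching and scoring,
    three-phase eligibility screening, covariate-adaptive randomization by
    minimization (Pocock-Simon), rate-limit-aware synchronization of wearable
    and smart-scale observation streams, rule-based adherence alerting, and
    CONSORT-style funnel and retention reporting. A seeded synthetic-data
    module emulates cohorts, questionnaire responses, and device vendor
    servers (including hourly API quotas and upload delays) so the full
    pipeline runs deterministically with no network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
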