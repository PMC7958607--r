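Package: rarfatigue
Title: Rest-Activity Rhythm Profiles and Perceived Physical Fatigability
Version: 0.1.0
Authors@R: person("RAR", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: A pipeline for relating wrist-accelerometry rest-activity
    rhythms (RARs) to perceived physical fatigability in older adults:
    minute-epoch count cleaning (midnight truncation, Choi-style non-wear
    detection, valid-day filters), antilogistic extended cosine modelling of
    the 24-h rhythm with derived mesor-crossing times and pseudo-F
    rhythmicity, localized time-bin activity metrics, k-means RAR profiling
    with semantic labels, and quantile (median) regression of Pittsburgh
    Fatigability Scale scores on rhythm features, plus a fully seeded
    synthetic-cohort generator so every stage is testable without
    participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
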