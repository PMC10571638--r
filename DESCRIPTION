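Package: audcage
Title: Behavioral Phenotyping of Alcohol Use Disorder-Like Behavior from
    IntelliCage Event Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for home-cage operant phenotyping of alcohol use disorder
    (AUD)-like behavior in mice. Reads IntelliCage-style event logs (visits,
    nosepokes, licks), computes five per-animal behavioral indices (motivation
    breakpoint on a progressive-ratio ladder, extinction responding,
    cue-induced relapse responding, first-day relapse alcohol intake in
    g/kg/day, and persistence of non-rewarded seeking), classifies animals as
    AUD-prone versus AUD-resistant by a top-quantile criterion rule and a
    composite z-score severity index, and characterizes the group-conditional
    correlation and principal-component structure of the behaviors. Includes an
    agent-based synthetic-cohort simulator with latent ground truth for
    validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
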