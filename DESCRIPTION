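Package: sinbscore
Title: Scoring, Simulation and Group Statistics for the Greek
    Speech-in-Babble Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the Greek Speech-in-Babble (SinB) speech-in-noise
    test. Computes the Spearman-Karber SNR50 threshold from trial-level
    responses under both word-based and syllable-based item scoring,
    simulates listener cohorts with logistic psychometric functions and
    correlated within-word syllable outcomes, and compares cohorts with
    normality screening, Cohen's d effect sizes, and mixed
    repeated-measures analysis of variance. Includes a command-line
    pipeline tying simulation, scoring and analysis together with
    reproducible manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
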