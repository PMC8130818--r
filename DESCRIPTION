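Package: sentitrace
Title: Hybrid Rule-Based Ensemble Sentiment Surveillance for Social Media Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for lexicon rule-based
    sentiment surveillance of social media posts about health interventions
    (the motivating use case is public perception of COVID-19 contact tracing
    apps). Provides strict readers/writers for post corpora, two-step thematic
    keyword filtering with date/language/region windows, two continuous
    valence-lexicon scoring channels, a weighted-average hybrid ensemble with
    rule-based fusion against a pluggable contextual classifier channel,
    grid-search weight tuning with confusion-matrix validation, weekly and
    county-level sentiment aggregation, term-frequency (word-cloud) tables,
    and a seeded synthetic two-platform corpus generator with known ground
    truth for testing every stage without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
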