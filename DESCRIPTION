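Package: osgcohesion
Title: Group-Cohesion Detection and Monitoring for Text-Based Online Support Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects expressions of group cohesion (warmth, mutual support,
    belonging, "we-talk") in transcripts of therapist-facilitated, text-based
    online support groups. Messages are scored by a TF-IDF n-gram ensemble of
    five classifiers combined by 2-of-3 majority voting with F1-weighted
    confidence, adjusted by hand-coded linguistic rules (negation, past tense,
    empathy, intensifiers), and aggregated into interval-level cohesion scores
    over a session timeline. Includes a word-embedding module that expands seed
    cohesion keywords into contextually similar expressions, a wildcard
    dictionary-category baseline in the style of closed-vocabulary text
    analysis tools, an active-learning loop that retrains from human-scored
    feedback, and a synthetic labeled-transcript generator for end-to-end
    testing when real chat data are private.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    glmnet,
    jsonlite,
    Matrix,
    methods,
    ranger,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
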