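Package: tweettrends
Title: Topic and Emotion Trend Mining for Short-Text Social Media Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for mining discussion topics and
    emotional trends from large collections of short social-media texts
    (tweet-like records). Topics are learned with online nonnegative
    matrix factorization (mini-batch dictionary learning) over a tf-idf
    encoded corpus; sentiment is assigned in two steps, a rule-based
    lexicon polarity score followed by polarity-gated zero-shot emotion
    classification via cosine similarity between text embeddings and
    emotion-word anchors; topic and emotion shares are tracked as daily
    and weekly time series and tested for stationarity with the
    augmented Dickey-Fuller test. A synthetic corpus generator with
    planted topics and emotions makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    graphics,
    jsonlite,
    methods,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
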