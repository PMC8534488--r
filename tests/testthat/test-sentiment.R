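test_that("compound score follows the s/sqrt(s^2+15) normalization exactly", {
  lex <- default_lexicon()
  expect_equal(polarity_compound("", lex), 0)
  expect_equal(polarity_compound("nothing matches here", lex), 0)
  # "good" has valence 2.0 in the bundled lexicon
  expect_equal(polarity_compound("good", lex), 2 / sqrt(19), tolerance = 1e-9)
  expect_equal(round(polarity_compound("good", lex), 4), 0.4588)
  # sign preservation for purely negative words
  expect_lt(polarity_compound("terrified and devastated", lex), 0)
  # additivity of matched valences: good (2.0) + great (2.4)
  s <- 4.4
  expect_equal(polarity_compound("good and great", lex), s / sqrt(s^2 + 15),
               tolerance = 1e-9)
})

test_that("negation flips and boosters amplify matched valences", {
  lex <- default_lexicon()
  expect_lt(polarity_compound("not good", lex), 0)
  expect_gt(polarity_compound("not bad", lex), 0)
  expect_gt(polarity_compound("very good", lex), polarity_compound("good", lex))
  # modifiers can be disabled
  expect_equal(polarity_compound("not good", lex, negators = NULL),
               polarity_compound("good", lex))
})

test_that("polarity labels use inclusive thresholds at plus/minus 0.05", {
  expect_equal(polarity_label(-0.05), "negative")
  expect_equal(polarity_label(0.05), "positive")
  expect_equal(polarity_label(0.049), "neutral")
  expect_equal(polarity_label(-0.049), "neutral")
  expect_equal(polarity_label(0), "neutral")
  # monotone: increasing compound never moves the label toward negative
  grid <- seq(-1, 1, by = 0.01)
  ord <- c(negative = 1, neutral = 2, positive = 3)
  expect_true(all(diff(ord[polarity_label(grid)]) >= 0))
})

test_that("cosine similarity handles the canonical and degenerate cases", {
  u <- c(1, 2, 3)
  expect_equal(cosine_similarity(u, u), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(u, -u), -1)
  expect_equal(cosine_similarity(u, rep(0, 3)), 0)
  expect_error(cosine_similarity(u, c(1, 2)), "mismatch")
  # scale invariance under positive rescaling
  expect_equal(cosine_similarity(3.7 * u, 0.2 * c(3, 1, 2)),
               cosine_similarity(u, c(3, 1, 2)), tolerance = 1e-12)
})

test_that("the toy embedder maps emotion-lexicon words onto the emotion axes", {
  emb <- toy_embedder()
  anchors <- emotion_anchors(emb)
  # pure fear text lands exactly on the fear axis
  v <- embed_text("terrified dread panic", emb)[1, ]
  expect_equal(unname(v), c(0, 1, 0, 0, 0))
  expect_equal(cosine_similarity(v, anchors["fear", ]), 1)
  # no lexicon words -> zero vector
  expect_equal(unname(embed_text("w001 w002", emb)[1, ]), rep(0, 5))
  # 2 joy words + 1 hopefulness word: joy wins the cosine ranking
  v2 <- embed_text("delighted thrilled hopeful", emb)[1, ]
  expect_gt(cosine_similarity(v2, anchors["joy", ]),
            cosine_similarity(v2, anchors["hopefulness", ]))
  # determinism
  expect_identical(embed_text("delighted w001", emb), embed_text("delighted w001", emb))
  expect_error(get_embedder("no-such-embedder"), "unknown")
})

test_that("gated classification restricts candidates by polarity and breaks ties low", {
  emb <- toy_embedder()
  expect_equal(classify_emotion("delighted", "neutral", emb), "neutral")
  expect_equal(classify_emotion("delighted thrilled hopeful", "positive", emb), "joy")
  # equal anger and fear cosines -> anger by the fixed order
  expect_equal(classify_emotion("furious afraid", "negative", emb), "anger")
  # negative polarity can never yield a positive emotion even if joy words dominate
  expect_equal(classify_emotion("delighted livid", "negative", emb), "anger")
})

test_that("global mode ranks all five cosines against the compound in the neutral slot", {
  emb <- toy_embedder()
  lab <- classify_emotion("furious rage", "negative", emb, mode = "global",
                          compound = -0.9)
  expect_equal(lab, "anger")
  # a compound above every cosine captures the document as neutral
  lab2 <- classify_emotion("furious delighted afraid grieving hopeful", "positive",
                           emb, mode = "global", compound = 0.99)
  expect_equal(lab2, "neutral")
})

test_that("emotion_matrix runs the two-step pipeline over a collection", {
  emb <- toy_embedder()
  lex <- default_lexicon()
  col <- make_collection(c("w001 w002 w003", "terrified dread w004", "delighted w005"))
  em <- emotion_matrix(col, lex, emb)
  expect_equal(dim(em$X), c(6, 3))
  expect_equal(em$X_rep, c("neutral", "fear", "joy"))
  expect_equal(em$polarity, c("neutral", "negative", "positive"))
  # non-neutral rows are cosines in [-1, 1]
  expect_true(all(em$X[1:5, ] >= -1 & em$X[1:5, ] <= 1))
  # neutral row carries the compound score
  expect_equal(unname(em$X["neutral", ]), em$compound)
  empty <- make_collection(character(0), times = numeric(0), ids = character(0))
  expect_error(emotion_matrix(empty, lex, emb), "empty")
})

test_that("gating partition holds on a full synthetic corpus", {
  fx <- easy_fixture()
  lex <- emotion_sentiment_lexicon(fx$gen$truth$lexicons)
  emb <- toy_embedder(fx$gen$truth$lexicons)
  em <- emotion_matrix(fx$gen$collection, lex, emb)
  pos <- em$polarity == "positive"
  neg <- em$polarity == "negative"
  neu <- em$polarity == "neutral"
  expect_false(any(em$X_rep[pos] %in% negative_emotions()))
  expect_false(any(em$X_rep[neg] %in% positive_emotions()))
  expect_true(all(em$X_rep[neu] == "neutral"))
  .fixtures$easy_emotions <- em
})
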