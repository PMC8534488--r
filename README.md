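# tweettrends

Topic and emotion trend mining for short-text social-media corpora.

Public-health teams monitoring vaccine discourse need to know *what*
people are discussing and *how they feel about it*, day by day, across
millions of short posts. `tweettrends` implements that analysis as a
tested, reusable R pipeline:

1. **Corpus handling** — read tweet-like records (JSONL/CSV), retain
   posts matching a keyword list (the shipped default is a 21-entry
   vaccine list of brand names, generic terms and hashtags), restrict
   to a UTC date window, filter by language metadata, and collapse
   retweets/exact duplicates.
2. **Encoding** — tokenize and build the sparse tf-idf corpus matrix
   `V ∈ R^(F×N)` with `v_ij = n_ij · ln(N / N⁽ⁱ⁾)`, where `n_ij` is
   the count of word `i` in document `j` and `N⁽ⁱ⁾` its document
   frequency.
3. **Topic detection** — online nonnegative matrix factorization
   (mini-batch dictionary learning): `V ≈ W H` with `W, H ≥ 0`, fitted
   over sequential document batches (per batch, solve `H` with the
   previous dictionary fixed, then refresh `W`; multiplicative
   updates, unit-norm dictionary columns). Each document's
   representative topic is `argmax_k H_kj`; topics whose share of
   documents falls below the average `1/K` are discarded as
   insignificant.
4. **Two-step sentiment** — a rule-based lexicon compound score
   `s/√(s²+15)` classified at the inclusive `±0.05` thresholds into
   negative/neutral/positive, then polarity-gated zero-shot emotion
   classification: cosine similarity between a text embedding and
   embeddings of the five emotion words (anger, fear, sadness, joy,
   hopefulness), with positive texts choosing between joy and
   hopefulness and negative texts among anger, fear and sadness.
5. **Trends** — daily topic shares and per-day emotion proportions
   (summing to 1 wherever there is volume), 7-day centered rolling
   means, and augmented Dickey-Fuller stationarity tests
   (constant-only regression, AIC lag selection, MacKinnon
   approximate p-values).

Because platform terms prevent redistributing a real tweet corpus, the
package ships a synthetic generator (`generate_corpus()`,
`corpus_presets()`) that plants topics, emotions and temporal regimes
with known ground truth, plus a deterministic `toy_embedder()` that
stands in for a sentence encoder; every stage is exercised end to end
against that ground truth. Pretrained transformer embedders plug in
through `register_embedder()`.

## Worked example

```r
library(tweettrends)

gen <- generate_corpus(corpus_presets("easy"))   # 2000 docs, 5 planted topics
col <- gen$collection
docs  <- tokenize(col$records$text)
vocab <- build_vocabulary(docs, min_df = 2, max_df_frac = 0.95)
V     <- tfidf_matrix(docs, vocab, doc_ids = col$records$id)
print(V)
#> <tfidf_matrix> 221 words x 2000 documents, 26356 nonzeros

fit <- onmf(V, k = 8, batch_size = 500, seed = 42)
assign <- assign_topics(predict(fit, V))
ratios <- topic_ratios(assign)
round(ratios, 3)
#> [1] 0.194 0.110 0.074 0.136 0.208 0.122 0.088 0.068
filter_topics(ratios)          # topics at or above the 1/8 average share
#> [1] 1 4 5
top_words(fit, 1, 5)
#>   word    weight
#> 1 w031 0.4145882
#> 2 w034 0.4096867
#> 3 w040 0.3711532
#> 4 w035 0.3063913
#> 5 w032 0.2873633

match_topics(gen$truth$topic_word, coef(fit))$mean_cosine
#> [1] 0.914          # mean best-match cosine against the planted topics

em <- emotion_matrix(col, emotion_sentiment_lexicon(gen$truth$lexicons),
                     toy_embedder(gen$truth$lexicons))
print(em)
#> <emotion_matrix> 2000 documents, mode = gated
#>       anger        fear     sadness         joy hopefulness     neutral
#>         3.6        38.0         5.5        23.2        11.1        18.5
mean(em$X_rep == gen$truth$doc$emotion)
#> [1] 1              # planted emotions recovered exactly

tab <- merge_topic_emotion(assign, em, col)
adf_test(daily_emotion_series(tab)$fear)
#> Augmented Dickey-Fuller test (constant, no trend)
#>   tau = -4.2695, lag order = 3, n = 60
#>   p-value = 0.0005 -> stationary at alpha = 0.05
```

The topic ratios show three learned columns comfortably above the
`1/K` cutoff (the planted topics split across the extra dictionary
capacity is discussed in the methods vignette); the emotion table
reproduces the planted mixture (fear dominant, joy second), and the
fear share is stationary over the 60-day window, as planted.

The same analysis runs stage-by-stage on files via `run_stage()` /
`run_pipeline()` (artifacts `corpus.jsonl`, `vocab.tsv`, `V.mtx`,
`W.mtx`, `topics.tsv`, `sentiment.tsv`, `trends.tsv`, `adf.tsv`,
`report.md`, each stamped with a configuration hash), or from a shell
via `inst/scripts/trendpipe.R`.

## Vignette

`vignettes/topic-emotion-trends.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, numerical
choices (tie-breaking, degenerate inputs, tolerances), and known
limitations.
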