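---
title: "Topic and emotion trend mining: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topic and emotion trend mining: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tweettrends)
```

## The analysis

`tweettrends` mines a corpus of short, timestamped social-media texts
for (i) its discussion topics, (ii) the emotional tone of each text,
and (iii) how topic and emotion shares evolve over a study window.
The canonical application is vaccine discourse monitoring: a 60-day
window of keyword-filtered, deduplicated, English tweets, encoded as
a tf-idf matrix, factorized into topics with online NMF, classified
into five emotions through a polarity-gated zero-shot scheme, and
tracked as daily/weekly time series tested for stationarity.

This vignette records the modelling assumptions, the tunable
parameters with their defaults and rationale, the numerical choices,
and what the synthetic test bed does and does not demonstrate.

## Corpus handling

Filters are record-local predicates (keyword, window, language) plus
one global reduction (deduplication), so the record-local filters
commute; the canonical order applies deduplication last. Keyword
matching is lowercase substring matching — phrases as contiguous
substrings, `#`-prefixed entries as literal hashtag substrings. This
reproduces the inclusion of inflected and hashtag forms without a
tokenizer dependency; the cost, deliberate, is that "vaccine" also
matches "vaccines". Deduplication normalizes texts (a leading
`RT @handle:` prefix is stripped, whitespace collapsed, case folded)
and keeps the earliest record of each exact-duplicate group, ties
broken by smallest id. Nothing fuzzier is attempted: near-duplicate
hashing would add a dependency and a threshold for little gain on the
retweet-dominated duplication the normalization targets. Quote-posts
with added commentary are *not* duplicates under this rule.
Timestamps are interpreted in UTC and both window endpoints are
inclusive (2020-12-16 through 2021-02-13 spans exactly 60 calendar
days). Language filtering trusts the platform's `lang` metadata;
records without metadata are retained by default since dropping them
silently biases volume.

## Encoding: tf-idf

The corpus matrix `V` has `F` word rows and `N` document columns with

    v_ij = n_ij * ln(N / N^(i))

the classical unsmoothed form: `n_ij` the count of word `i` in
document `j`, `N^(i)` the number of documents containing `i`. A word
present in every document is weighted exactly zero. The natural
logarithm is a pure rescaling absorbed by the factorization, so the
base is not a real parameter. A smoothed variant
(`ln((1+N)/(1+N^(i))) + 1`) and optional L2 column normalization are
available behind arguments for corpora where ubiquitous words should
retain weight, but the unsmoothed form is the default because it
matches the interpretation that a word frequent in one tweet but rare
corpus-wide is the tweet's important word.

Tokenization follows standard short-text practice: lowercase; URLs
and `@`-mentions removed; hashtags kept as their bare word (the tag
is topical content); punctuation stripped; tokens shorter than 2
characters and stopwords removed. The stopword list ships as a
plain-text file and every step is an argument — emoji and encoding
quirks beyond these rules are out of scope. Vocabulary pruning
defaults, `min_df = 2` and `max_df_frac = 0.95` in the pipeline,
drop hapax noise and near-ubiquitous words before factorization.

## Online NMF

`onmf()` minimizes `||V - W H||_F` with `W, H >= 0` by streaming
document batches: for batch `q`, solve `H^q` with `W^(q-1)` fixed,
then refresh `W^q` with `H^q` fixed. Both inner solves use
multiplicative updates, which keep factors nonnegative and never
increase the objective — the per-batch objective traces are stored in
the fit and asserted non-increasing in the tests. An explicit
nonnegative-least-squares solve (`pracma::lsqnonneg`, Lawson-Hanson)
is used at inference time (`predict()`), per document column, because
inference should not depend on an iteration budget.

Parameters and defaults:

* `k` (topics): 50 in the production configuration. The package never
  chooses `k` by model selection — that is a non-goal; synthetic runs
  use `k = 8` over 5 planted topics to exercise the ratio filter.
* `batch_size` (`s`): 2000. Memory per batch scales with `F × s`.
* `inner_iters` = 100 with relative-change tolerance `tol = 1e-4`:
  enough for the per-batch subproblems to stabilize without
  dominating runtime; the oracle-equivalence test raises this
  (300 iterations, 8 passes, `tol = 1e-6`) so both the online fit and
  the reference batch fit are close to converged before comparison.
* `passes`: 1 — a genuinely online fit sees each document once. More
  passes are allowed and improve the fit on small corpora.
* Initialization: dictionary entries uniform(0,1) from `seed`;
  document order is taken as read (no shuffling) so fits are exactly
  reproducible given seed and input order.

After every batch the dictionary columns are rescaled to unit L2 norm
with compensating row scaling of `H`. This changes nothing about the
product `W H` but removes the scale ambiguity, making the argmax
representative topic and the top-word rankings well defined.

Representative topics: `argmax_k H_kj`, ties broken by the smallest
topic index; an all-zero loading column (a document with only
out-of-vocabulary words) is left unassigned rather than silently
assigned to topic 1, and unassigned documents are excluded from the
topic-ratio denominator. The ratio filter keeps topics whose share is
at or above the average `1/k` (equality kept, so a perfectly uniform
assignment keeps everything); with `k = 50` that is the 2% cutoff
that discards insignificant topics.

### Validating recovery, and a caveat about overcapacity

On the easy synthetic preset the fitted dictionary recovers the
planted topic-word vectors with mean best-match cosine 0.90-0.95
(greedy one-to-one matching). The ratio *filter* is validated on the
ground-truth representative assignment embedded at `k = 8`: planted
shares near 1/5 each, three structurally empty slots, so the filter
retains exactly the planted set. It is validated this way because
multiplicative-update NMF given more columns than planted topics does
not leave the surplus columns near-empty — they *split* a planted
anchor block into complementary halves, a well-known behaviour of
overcomplete NMF. After splitting, one planted topic's documents
divide across two columns and either column's share can dip just
below `1/k`. The phenomenon being emulated — a large corpus where
most of 50 fitted topics attract a below-average share — lives at the
assignment level, not in the fitted dictionary of a 5-topic toy
corpus, and the test reflects that.

## Two-step sentiment

**Step 1 — polarity.** A rule-based lexicon scorer: sum the valences
`s` of matched tokens and squash to `compound = s / sqrt(s^2 + 15)`,
clamped to `[-1, 1]`; a text with no lexicon match scores exactly 0.
Two modifier rules, both optional arguments: a valence's sign flips
when one of the two preceding tokens is a negator, and it is scaled
by 1.293 when the immediately preceding token is a booster. The
scorer is deliberately the simple, exactly testable contract — the
lexicon is pluggable (TSV of token/valence), and the bundled mini
lexicon is small and versioned so unit tests are exact. Labels use
the social-media rule-based convention with *inclusive* boundaries:
`<= -0.05` negative, `>= +0.05` positive, otherwise neutral. The
mapping is monotone in the compound score.

**Step 2 — emotion.** Emotions are assigned zero-shot: embed the text
and the five bare emotion words (anger, fear, sadness, joy,
hopefulness) with the same embedder and rank cosine similarities.
The default `gated` mode restricts candidates by polarity — neutral
stays neutral, positive chooses between joy and hopefulness, negative
among anger, fear and sadness — because the two-emotion/three-emotion
split is exactly what the gating expresses, and it guarantees the
partition invariant (no positive text is ever labelled angry). A
`global` mode is kept as an alternative: argmax over all five cosines
with the compound score standing in the neutral slot. That mode mixes
a cosine scale with a compound scale in one argmax — a comparability
caveat documented rather than hidden, which is why it is not the
default. Ties break in the fixed order anger, fear, sadness, joy,
hopefulness. A zero text embedding yields neutral with a warning.

Anchors are the bare emotion words by default; a template argument
(`"this text expresses %s"`) exists for sentence-level embedders that
degrade on single words. No transformer ships with the package: an
embedder is any registered deterministic function from text to a
fixed-length vector, and the deterministic 5-dimensional
`toy_embedder()` (lexicon word counts per emotion, L2-normalized)
serves the test bed.

## Trends and stationarity

Daily series are built per UTC calendar day over the table's full
span. Emotion proportions are computed within scope (overall or one
topic) over six labels — the five emotions plus neutral — and sum to
1 on every day with volume. Days with zero volume yield *missing*
values, not zeros: silence carries no sentiment, and imputing zeros
would manufacture stationarity-breaking structure. "Weekly" curves
are centered 7-day rolling means with shrinking windows at the
boundaries (a calendar-week aggregation would produce one point per
week; the rolling mean keeps daily resolution, which is what the
trend plots need).

`adf_test()` implements the augmented Dickey-Fuller regression with a
constant and no deterministic trend term: daily proportions have a
nonzero mean, and no trend specification is assumed a priori — a
genuinely drifting series should *fail* to reject the unit root, and
does. Lag order is selected by AIC over `0..floor((n-1)^(1/3))` on a
common estimation sample, then the chosen order is refit on the full
usable sample; p-values use the MacKinnon approximate asymptotic
response surface for the constant-only case. The implementation was
cross-checked against an independent reference implementation on
fixed-seed white-noise and random-walk series (statistics agree to
eight decimals; those values are frozen in the test suite). The test
runs on *raw daily proportions* — smoothing before testing would
induce spurious autocorrelation. Constant series are rejected with a
zero-variance error and short series (fewer than 10 points) with a
length error rather than returning fragile statistics.

## The synthetic test bed

`generate_corpus()` plants everything the pipeline is supposed to
find. Per document: one topic from `K_true` planted topic-word
distributions (Dirichlet base measure plus a boosted block of anchor
words), tokens drawn from that distribution, one emotion from the
day's mixture with 1-3 distinct words of that emotion's lexicon
injected verbatim, and a timestamp uniform within its day. Defaults,
chosen once:

* `K_true = 5`, 200-word vocabulary, 10 anchors per topic,
  `anchor_mass = 0.7` — well-separated topics a factorization should
  find.
* `doc_len_mean = 18` (Poisson, floored at 3): enough topic tokens
  that the planted topic, not the 1-3 injected emotion words,
  dominates each document's tf-idf geometry — the "single dominant
  topic per document" semantics the argmax representative topic
  presumes.
* Baseline emotion mixture: fear 0.38, joy 0.22, neutral 0.20,
  hopefulness 0.11, sadness 0.05, anger 0.04 — the share profile of
  large vaccine-discourse corpora (fear dominant, joy second).
* Presets: `easy` (N = 2000, stationary mixture, recovery testing),
  `stationary` (N = 6000, i.e. ~100 documents/day, so daily shares
  have multinomial noise ~0.04 and the ADF verdicts are stable), and
  `drift` (as stationary, but sadness rises linearly 0.05 to 0.25
  across the window, the one-emotion-drifts regime).

The emotion lexicons are pairwise disjoint and injected verbatim, and
the toy embedder counts exactly those words — so polarity recovery
(the injected valences force the compound sign) and emotion recovery
are near-perfect *by construction*. That is the point: the test bed
verifies the machinery, plumbing and contracts. Passing it does
**not** show that real tweets are classified this well: real language
has sarcasm, negated emotion words outside the lexicons, topic-word
and emotion-word overlap, near-duplicates that are not retweets, and
an embedder whose geometry is nothing like coordinate axes. Scale is
also reduced by design: the test corpora (2000-6000 documents, the
50×500 oracle matrix) exercise every code path in seconds while the
production configuration (`k = 50`, `s = 2000`) is exactly the same
code on more columns.

## Known limitations

* No language identification, bot detection or near-duplicate
  hashing; the corpus filters trust metadata and exact (normalized)
  duplication.
* The lexicon scorer is a contract implementation, not a full
  social-media sentiment engine (no emoji, ALL-CAPS or punctuation
  emphasis rules); heavier scorers can be swapped in via the lexicon
  and modifier arguments.
* `k` must be supplied; no model selection.
* The global emotion mode compares a compound score against cosines
  on different scales; retained for completeness, not recommended.
* The ADF test assumes an internally complete series; silent days
  are dropped (with their dates) before testing, which is only
  defensible when silent days are rare.
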