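# Shared fixtures, built lazily and cached for the whole test run.
.fixtures <- new.env(parent = emptyenv())

# Easy-preset corpus with its tf-idf encoding (the recovery backbone).
easy_fixture <- function() {
  if (is.null(.fixtures$easy)) {
    gen <- generate_corpus(corpus_presets("easy"))
    docs <- tokenize(gen$collection$records$text)
    vocab <- build_vocabulary(docs, min_df = 2, max_df_frac = 0.95)
    V <- tfidf_matrix(docs, vocab, doc_ids = gen$collection$records$id)
    .fixtures$easy <- list(gen = gen, docs = docs, vocab = vocab, V = V)
  }
  .fixtures$easy
}

# Small hand-built collection.
make_collection <- function(texts,
                            times = seq_along(texts),
                            ids = sprintf("d%02d", seq_along(texts)),
                            lang = "en") {
  lang <- rep(lang, length.out = length(texts))
  if (is.numeric(times)) {
    times <- as.POSIXct("2020-12-16 00:00:00", tz = "UTC") + times * 3600
  }
  tweet_collection(data.frame(id = ids, created_at = times, text = texts,
                              lang = lang, stringsAsFactors = FALSE))
}

# Independent reference: plain batch multiplicative-update NMF, dense,
# alternating one H and one W update per iteration.
batch_nmf_oracle <- function(V, k, iters, seed) {
  set.seed(seed)
  f <- nrow(V); n <- ncol(V)
  W <- matrix(stats::runif(f * k), f, k)
  H <- matrix(stats::runif(k * n), k, n)
  eps <- .Machine$double.eps
  for (it in seq_len(iters)) {
    H <- H * crossprod(W, V) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
  }
  list(W = W, H = H, objective = sqrt(sum((V - W %*% H)^2)))
}
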