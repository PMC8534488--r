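#' Default planted emotion lexicons
#'
#' Six to seven valenced words per emotion, pairwise disjoint, used by
#' the synthetic generator (injected verbatim into documents) and by
#' the [toy_embedder()]. The disjointness makes emotion recovery
#' analytically tractable: realism is deliberately traded for
#' testability.
#'
#' @return Named list (one element per emotion) of named numeric
#'   valence vectors.
#' @export
default_emotion_lexicons <- function() {
  list(
    anger = c(furious = -2.2, outraged = -2.4, rage = -2.6, angry = -2.0,
              infuriating = -2.3, livid = -2.5),
    fear = c(afraid = -1.9, terrified = -2.7, scared = -2.0,
             frightening = -2.2, panic = -2.1, dread = -2.3),
    sadness = c(heartbroken = -2.4, grieving = -2.2, mourning = -2.0,
                sorrow = -2.1, devastated = -2.5, tearful = -1.8),
    joy = c(delighted = 2.3, thrilled = 2.5, wonderful = 2.4,
            fantastic = 2.6, joyful = 2.2, celebrating = 2.0),
    hopefulness = c(hopeful = 1.9, optimistic = 2.1, promising = 1.8,
                    reassuring = 1.7, encouraged = 2.0, uplifting = 1.9)
  )
}

#' Flatten emotion lexicons into a sentiment lexicon
#'
#' @param lexicons A [default_emotion_lexicons()]-shaped list.
#' @return A [sentiment_lexicon()] of all words with their valences.
#' @export
emotion_sentiment_lexicon <- function(lexicons = default_emotion_lexicons()) {
  sentiment_lexicon(unlist(unname(lexicons)))
}

# Baseline emotion mixture emulating the shares observed in large
# vaccine-discussion corpora: fear dominant, joy second, sizable
# neutral volume, smaller hopefulness/sadness/anger.
default_emotion_mix <- function() {
  c(anger = 0.04, fear = 0.38, sadness = 0.05,
    joy = 0.22, hopefulness = 0.11, neutral = 0.20)
}

#' Synthetic corpus configuration
#'
#' Describes a tweet-like corpus with planted structure: each document
#' carries one dominant topic drawn from `K_true` planted topic-word
#' distributions (Dirichlet over the vocabulary with a boosted block
#' of anchor words per topic), one planted emotion drawn from that
#' day's emotion mixture (with 1-3 matching emotion-lexicon words
#' injected verbatim), and a timestamp uniform within its day.
#'
#' @param K_true Number of planted topics.
#' @param vocab_size Topic vocabulary size.
#' @param anchors_per_topic Anchor words per topic (disjoint blocks).
#' @param anchor_mass Probability mass a topic places on its anchors.
#' @param doc_len_mean Mean document length in topic words (Poisson,
#'   floored at 3).
#' @param n_docs Number of documents `N`.
#' @param start_date First calendar day (UTC).
#' @param n_days Number of days (default 60).
#' @param topic_mix Topic mixture `pi` (length `K_true`, sums to 1).
#' @param emotion_lexicons Planted per-emotion word lexicons
#'   (pairwise disjoint).
#' @param emotion_trends Named list, one entry per label in
#'   `c(emotion_labels(), "neutral")`; each either
#'   `list(type = "stationary", p = )` or
#'   `list(type = "drift", p0 = , p1 = )` (linear across the window).
#'   Daily mixtures are renormalized to sum to 1.
#' @param seed RNG seed; generation is fully deterministic given the
#'   config.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(K_true = 5L, vocab_size = 200L,
                             anchors_per_topic = 10L, anchor_mass = 0.7,
                             doc_len_mean = 18, n_docs = 2000L,
                             start_date = "2020-12-16", n_days = 60L,
                             topic_mix = rep(1 / K_true, K_true),
                             emotion_lexicons = default_emotion_lexicons(),
                             emotion_trends = NULL, seed = 1L) {
  stopifnot(K_true >= 1, vocab_size >= K_true * anchors_per_topic,
            anchors_per_topic >= 1, anchor_mass > 0, anchor_mass < 1,
            doc_len_mean >= 3, n_docs >= 1, n_days >= 1,
            length(topic_mix) == K_true)
  if (abs(sum(topic_mix) - 1) > 1e-8) stop("topic_mix must sum to 1")
  if (any(topic_mix < 0)) stop("topic_mix must be nonnegative")
  words <- unlist(lapply(emotion_lexicons, names))
  if (anyDuplicated(words)) stop("emotion lexicons must be pairwise disjoint")
  labels <- c(emotion_labels(), "neutral")
  if (is.null(emotion_trends)) {
    mix <- default_emotion_mix()
    emotion_trends <- lapply(labels, function(l) list(type = "stationary", p = mix[[l]]))
    names(emotion_trends) <- labels
  }
  if (!setequal(names(emotion_trends), labels)) {
    stop("emotion_trends must name exactly: ", paste(labels, collapse = ", "))
  }
  for (tr in emotion_trends) {
    ps <- if (tr$type == "stationary") tr$p else c(tr$p0, tr$p1)
    if (any(ps < 0 | ps > 1)) stop("emotion trend probabilities must lie in [0, 1]")
  }
  structure(list(K_true = as.integer(K_true), vocab_size = as.integer(vocab_size),
                 anchors_per_topic = as.integer(anchors_per_topic),
                 anchor_mass = anchor_mass, doc_len_mean = doc_len_mean,
                 n_docs = as.integer(n_docs), start_date = as.Date(start_date),
                 n_days = as.integer(n_days), topic_mix = topic_mix,
                 emotion_lexicons = emotion_lexicons,
                 emotion_trends = emotion_trends, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Daily emotion mixture schedule: n_days x 6 matrix, rows sum to 1.
emotion_schedule <- function(config) {
  labels <- c(emotion_labels(), "neutral")
  n <- config$n_days
  raw <- sapply(labels, function(l) {
    tr <- config$emotion_trends[[l]]
    if (tr$type == "stationary") {
      rep(tr$p, n)
    } else if (tr$type == "drift") {
      if (n == 1) tr$p0 else tr$p0 + (tr$p1 - tr$p0) * (seq_len(n) - 1) / (n - 1)
    } else stop("unknown trend type: ", tr$type)
  })
  raw <- matrix(raw, nrow = n, dimnames = list(NULL, labels))
  sweep(raw, 1, rowSums(raw), "/")
}

#' Generate a synthetic tweet-like corpus with planted ground truth
#'
#' @param config A [synthetic_config()].
#' @return List with `collection` (a [tweet_collection()] in the JSONL
#'   schema of [read_tweets()]) and `truth` (class `ground_truth`:
#'   per-document planted topic/emotion/polarity, the true topic-word
#'   matrix, the daily emotion mixture schedule, the lexicons and the
#'   config).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  vocab <- sprintf("w%03d", seq_len(config$vocab_size))
  K <- config$K_true
  labels <- c(emotion_labels(), "neutral")

  # planted topic-word distributions: Dirichlet base + anchor block
  topic_word <- matrix(0, K, config$vocab_size,
                       dimnames = list(paste0("topic", seq_len(K)), vocab))
  for (k in seq_len(K)) {
    base <- stats::rgamma(config$vocab_size, shape = 0.2)
    base <- base / sum(base)
    anchors <- (k - 1) * config$anchors_per_topic + seq_len(config$anchors_per_topic)
    aw <- stats::rgamma(config$anchors_per_topic, shape = 5)
    beta <- (1 - config$anchor_mass) * base
    beta[anchors] <- beta[anchors] + config$anchor_mass * aw / sum(aw)
    topic_word[k, ] <- beta / sum(beta)
  }

  schedule <- emotion_schedule(config)
  n <- config$n_docs
  day <- sample.int(config$n_days, n, replace = TRUE)
  topic <- sample.int(K, n, replace = TRUE, prob = config$topic_mix)
  doc_len <- pmax(3L, stats::rpois(n, config$doc_len_mean))
  emotion <- vapply(day, function(d) sample(labels, 1, prob = schedule[d, ]), "")
  polarity <- ifelse(emotion %in% negative_emotions(), "negative",
                     ifelse(emotion %in% positive_emotions(), "positive", "neutral"))

  texts <- character(n)
  for (i in seq_len(n)) {
    tk <- sample(vocab, doc_len[i], replace = TRUE, prob = topic_word[topic[i], ])
    if (emotion[i] != "neutral") {
      lex <- names(config$emotion_lexicons[[emotion[i]]])
      tk <- c(tk, sample(lex, sample.int(3L, 1L)))
    }
    texts[i] <- paste(sample(tk), collapse = " ")
  }
  secs <- stats::runif(n, 0, 86399)
  created <- as.POSIXct(config$start_date, tz = "UTC") + (day - 1) * 86400 + secs
  records <- data.frame(
    id = sprintf("s%06d", seq_len(n)),
    created_at = created,
    text = texts,
    lang = "en",
    stringsAsFactors = FALSE
  )
  truth <- structure(list(
    doc = data.frame(id = records$id, day = day, topic = topic,
                     emotion = emotion, polarity = polarity,
                     stringsAsFactors = FALSE),
    topic_word = topic_word,
    schedule = schedule,
    lexicons = config$emotion_lexicons,
    config = config
  ), class = "ground_truth")
  list(collection = tweet_collection(records), truth = truth)
}

#' Deterministic toy text embedder
#'
#' A 5-dimensional embedder standing in for a pretrained sentence
#' encoder at test time: component i counts the words of emotion i's
#' lexicon (plus the bare emotion word itself) in the text, L2
#' normalized when nonzero. Embedding an emotion word therefore yields
#' exactly the unit basis vector of that emotion, so the emotion
#' anchors are the coordinate axes and cosine ranking is exact by
#' construction.
#'
#' @param lexicons Emotion lexicons, [default_emotion_lexicons()] by
#'   default.
#' @return An embedder object usable wherever an embedder name is
#'   accepted (see [register_embedder()]).
#' @export
toy_embedder <- function(lexicons = default_emotion_lexicons()) {
  labels <- emotion_labels()
  sets <- lapply(labels, function(l) c(names(lexicons[[l]]), l))
  names(sets) <- labels
  fn <- function(text) {
    tk <- polarity_tokens(text)
    v <- vapply(labels, function(l) sum(tk %in% sets[[l]]), 0)
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v / nrm else v
  }
  list(fn = fn, dim = 5L, name = "toy")
}

#' Named synthetic presets
#'
#' * `"easy"` — recovery testing: `K_true = 5`, 200-word vocabulary,
#'   10 anchors per topic, `N = 2000` over 60 days, stationary
#'   emotion mixture.
#' * `"stationary"` — trend testing under a constant emotion mixture:
#'   `N = 6000` (about 100 documents/day) so daily shares are tight
#'   around the planted mixture.
#' * `"drift"` — as `"stationary"` but sadness' share rises linearly
#'   from 0.05 to 0.25 across the window while the others stay flat.
#'
#' @param name Preset name, or `NULL` for the full named list.
#' @return A [synthetic_config()] (or named list of them).
#' @export
corpus_presets <- function(name = NULL) {
  drift_trends <- local({
    mix <- default_emotion_mix()
    tr <- lapply(names(mix), function(l) list(type = "stationary", p = mix[[l]]))
    names(tr) <- names(mix)
    tr$sadness <- list(type = "drift", p0 = 0.05, p1 = 0.25)
    tr
  })
  presets <- list(
    easy = synthetic_config(n_docs = 2000L, seed = 101L),
    stationary = synthetic_config(n_docs = 6000L, seed = 202L),
    drift = synthetic_config(n_docs = 6000L, emotion_trends = drift_trends,
                             seed = 303L)
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop("unknown preset: ", name, " (available: ",
         paste(names(presets), collapse = ", "), ")")
  }
  presets[[name]]
}

#' Write ground truth to plain-text TSVs
#'
#' Emits `<stem>_docs.tsv` (per-document planted labels),
#' `<stem>_topic_word.tsv` (true topic-word matrix) and
#' `<stem>_lexicons.tsv` (emotion, token, valence).
#'
#' @param truth A `ground_truth` object.
#' @param stem Output path stem.
#' @return The three paths, invisibly.
#' @export
write_ground_truth <- function(truth, stem) {
  stopifnot(inherits(truth, "ground_truth"))
  p1 <- paste0(stem, "_docs.tsv")
  utils::write.table(truth$doc, p1, sep = "\t", row.names = FALSE, quote = FALSE)
  p2 <- paste0(stem, "_topic_word.tsv")
  tw <- data.frame(topic = rownames(truth$topic_word), truth$topic_word,
                   check.names = FALSE)
  utils::write.table(tw, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  p3 <- paste0(stem, "_lexicons.tsv")
  lex <- do.call(rbind, lapply(names(truth$lexicons), function(e) {
    data.frame(emotion = e, token = names(truth$lexicons[[e]]),
               valence = unname(truth$lexicons[[e]]), stringsAsFactors = FALSE)
  }))
  utils::write.table(lex, p3, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2, p3))
}
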