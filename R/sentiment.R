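#' Emotion label sets
#'
#' Five emotions plus neutral. The fixed order of `emotion_labels()`
#' (anger, fear, sadness, joy, hopefulness) is also the tie-breaking
#' order of the emotion classifier; positive polarity admits joy and
#' hopefulness, negative polarity admits anger, fear and sadness.
#'
#' @return Character vectors of labels.
#' @export
emotion_labels <- function() c("anger", "fear", "sadness", "joy", "hopefulness")

#' @rdname emotion_labels
#' @export
negative_emotions <- function() c("anger", "fear", "sadness")

#' @rdname emotion_labels
#' @export
positive_emotions <- function() c("joy", "hopefulness")

#' Read a sentiment lexicon from TSV
#'
#' @param path TSV file with columns `token` and `valence` (comment
#'   lines starting with `#` allowed).
#' @return Named numeric vector of token valences, class
#'   `sentiment_lexicon`.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("token", "valence") %in% names(df)))
  sentiment_lexicon(stats::setNames(as.numeric(df$valence), df$token))
}

#' Construct a sentiment lexicon
#'
#' @param valences Named numeric vector, token -> valence; tokens are
#'   lowercased, valences must be finite.
#' @return Object of class `sentiment_lexicon`.
#' @export
sentiment_lexicon <- function(valences) {
  stopifnot(is.numeric(valences), !is.null(names(valences)))
  if (any(!is.finite(valences))) stop("lexicon valences must be finite")
  names(valences) <- tolower(names(valences))
  if (anyDuplicated(names(valences))) stop("duplicate lexicon tokens")
  structure(valences, class = "sentiment_lexicon")
}

#' Bundled mini sentiment lexicon
#'
#' A small versioned lexicon (the synthetic emotion-lexicon words plus
#' a few generic valenced words) so polarity unit tests are exact.
#'
#' @return A [sentiment_lexicon()].
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "mini_sentiment_lexicon.tsv",
                           package = "tweettrends"))
}

default_negators <- function() {
  c("not", "no", "never", "none", "neither", "nobody", "cannot",
    "can't", "won't", "isn't", "aren't", "wasn't", "weren't", "don't",
    "doesn't", "didn't", "without")
}

default_boosters <- function() {
  c("very", "really", "extremely", "absolutely", "so", "totally", "incredibly")
}

# Simple word-level split used by the rule-based scorer (keeps
# apostrophes so contractions like "don't" survive).
polarity_tokens <- function(text) {
  x <- tolower(text)
  x <- gsub("https?://\\S+", " ", x)
  x <- gsub("[^a-z']+", " ", x)
  tk <- strsplit(trimws(x), "\\s+")[[1]]
  tk[nzchar(tk)]
}

#' Rule-based compound polarity score
#'
#' Sums the valences of lexicon-matched tokens, flipping the sign of a
#' valence when one of the two preceding tokens is a negator and
#' scaling it by 1.293 when the immediately preceding token is a
#' booster, then squashes the sum `s` to
#' `compound = s / sqrt(s^2 + 15)`, clamped to `[-1, 1]`. Texts with
#' no lexicon match score exactly 0.
#'
#' @param text Character vector.
#' @param lexicon A [sentiment_lexicon()]; [default_lexicon()] by
#'   default.
#' @param negators,boosters Modifier word sets; `NULL` disables the
#'   rule.
#' @return Numeric vector of compound scores in `[-1, 1]`.
#' @export
polarity_compound <- function(text, lexicon = default_lexicon(),
                              negators = default_negators(),
                              boosters = default_boosters()) {
  stopifnot(inherits(lexicon, "sentiment_lexicon"))
  vapply(text, function(txt) {
    tk <- polarity_tokens(txt)
    if (!length(tk)) return(0)
    s <- 0
    for (i in seq_along(tk)) {
      v <- unname(lexicon[tk[i]])
      if (is.na(v)) next
      prev <- tk[max(1L, i - 2L):max(1L, i - 1L)]
      if (i > 1L && !is.null(boosters) && tk[i - 1L] %in% boosters) v <- v * 1.293
      if (i > 1L && !is.null(negators) && any(prev %in% negators)) v <- -v
      s <- s + v
    }
    if (s == 0) return(0)
    max(-1, min(1, s / sqrt(s^2 + 15)))
  }, 0, USE.NAMES = FALSE)
}

#' Polarity label from a compound score
#'
#' Thresholds follow the rule-based social-media scorer convention:
#' `compound <= -0.05` is negative, `compound >= 0.05` is positive
#' (both boundaries inclusive), anything in between is neutral. The
#' mapping is monotone in the compound score.
#'
#' @param compound Numeric vector in `[-1, 1]`.
#' @return Character vector in `{negative, neutral, positive}`.
#' @export
polarity_label <- function(compound) {
  ifelse(compound <= -0.05, "negative",
         ifelse(compound >= 0.05, "positive", "neutral"))
}

# Embedder registry: name -> list(fn = function(character(1)) -> numeric(d),
# dim = d). Package-local environment.
.embedders <- new.env(parent = emptyenv())

#' Register / fetch a text embedder
#'
#' An embedder is a deterministic function from a single string to a
#' fixed-length numeric vector. The package ships no pretrained
#' transformer; sentence-encoder backends plug in through this
#' registry, and the deterministic [toy_embedder()] serves testing.
#'
#' @param name Embedder name.
#' @param fn Function `character(1) -> numeric(dim)`.
#' @param dim Embedding dimension.
#' @return `register_embedder` returns `name` invisibly;
#'   `get_embedder` the registered list.
#' @export
register_embedder <- function(name, fn, dim) {
  stopifnot(is.character(name), is.function(fn), dim >= 1)
  assign(name, list(fn = fn, dim = as.integer(dim)), envir = .embedders)
  invisible(name)
}

#' @rdname register_embedder
#' @export
get_embedder <- function(name) {
  if (is.list(name) && is.function(name$fn)) return(name)
  if (!exists(name, envir = .embedders, inherits = FALSE)) {
    stop("unknown embedder: ", name)
  }
  get(name, envir = .embedders, inherits = FALSE)
}

#' Embed a text
#'
#' @param text Character vector.
#' @param embedder Registered embedder name or an embedder object.
#' @return Numeric matrix, one row per text, `dim` columns.
#' @export
embed_text <- function(text, embedder) {
  e <- get_embedder(embedder)
  out <- t(vapply(text, function(tt) {
    v <- e$fn(tt)
    if (length(v) != e$dim || any(!is.finite(v))) {
      stop("embedder returned a malformed vector")
    }
    as.numeric(v)
  }, numeric(e$dim), USE.NAMES = FALSE))
  out
}

#' Cosine similarity
#'
#' `u . v / (||u|| ||v||)`, defined as 0 when either vector is zero.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("dimension mismatch in cosine similarity")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  max(-1, min(1, sum(u * v) / (nu * nv)))
}

#' Emotion anchor embeddings
#'
#' Embeds the five bare emotion words (or, optionally, a template
#' sentence around each) with the given embedder.
#'
#' @param embedder Embedder name or object.
#' @param template Optional template containing `%s`, e.g.
#'   `"this text expresses %s"`; by default the bare emotion word is
#'   embedded.
#' @return Matrix with one row per emotion (rownames =
#'   [emotion_labels()]).
#' @export
emotion_anchors <- function(embedder, template = NULL) {
  words <- emotion_labels()
  texts <- if (is.null(template)) words else sprintf(template, words)
  A <- embed_text(texts, embedder)
  rownames(A) <- words
  A
}

#' Polarity-gated zero-shot emotion classification
#'
#' Ranks the cosine similarities between a text's embedding and the
#' emotion-word anchor embeddings. In `"gated"` mode (default) the
#' candidate set is restricted by the polarity label: neutral texts
#' stay neutral, positive texts choose between joy and hopefulness,
#' negative texts between anger, fear and sadness. In `"global"` mode
#' the argmax runs over all five cosines plus the compound score
#' standing in the neutral slot. Ties are broken in the fixed order
#' anger, fear, sadness, joy, hopefulness.
#'
#' @param text Character vector.
#' @param polarity Polarity labels (from [polarity_label()]), recycled
#'   checks apply.
#' @param embedder Embedder name or object.
#' @param mode `"gated"` or `"global"`.
#' @param compound Compound scores, required in `"global"` mode.
#' @param anchors Optional precomputed [emotion_anchors()] matrix.
#' @return Character vector of labels in
#'   `{anger, fear, sadness, joy, hopefulness, neutral}`.
#' @export
classify_emotion <- function(text, polarity, embedder,
                             mode = c("gated", "global"),
                             compound = NULL, anchors = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(text) == length(polarity))
  if (mode == "global" && is.null(compound)) {
    stop("global mode needs the compound scores for the neutral slot")
  }
  if (is.null(anchors)) anchors <- emotion_anchors(embedder)
  E <- embed_text(text, embedder)
  labels <- emotion_labels()
  out <- character(length(text))
  for (j in seq_along(text)) {
    ev <- E[j, ]
    if (all(ev == 0)) {
      if (mode == "gated" && polarity[j] == "neutral") {
        out[j] <- "neutral"
      } else {
        warning("zero embedding for document ", j, "; labelled neutral")
        out[j] <- "neutral"
      }
      next
    }
    cs <- vapply(labels, function(l) cosine_similarity(ev, anchors[l, ]), 0)
    if (mode == "gated") {
      out[j] <- switch(polarity[j],
        neutral  = "neutral",
        positive = positive_emotions()[which.max(cs[positive_emotions()])],
        negative = negative_emotions()[which.max(cs[negative_emotions()])],
        stop("unknown polarity label: ", polarity[j])
      )
    } else {
      scores <- c(cs, neutral = compound[j])
      out[j] <- names(scores)[which.max(scores)]
    }
  }
  out
}

#' Emotion matrix and representative emotions for a corpus
#'
#' Runs the full two-step sentiment assignment over a collection: the
#' rule-based compound polarity score with its `± 0.05` label
#' thresholds, then the polarity-gated (or global) zero-shot emotion
#' classifier. The emotion matrix `X` has one row per emotion holding
#' cosine similarities in `[-1, 1]` plus a neutral row holding the
#' compound score; `X_rep` records each document's representative
#' emotion.
#'
#' @param col A [tweet_collection()] (nonempty).
#' @param lexicon A [sentiment_lexicon()].
#' @param embedder Embedder name or object.
#' @param mode `"gated"` (default) or `"global"`.
#' @return Object of class `emotion_matrix`: list with `X`
#'   (`6 x N`), `X_rep`, `compound`, `polarity`, `doc_ids`, `mode`.
#' @export
emotion_matrix <- function(col, lexicon = default_lexicon(), embedder,
                           mode = c("gated", "global")) {
  mode <- match.arg(mode)
  stopifnot(inherits(col, "tweet_collection"))
  if (!nrow(col$records)) stop("empty collection")
  text <- col$records$text
  comp <- polarity_compound(text, lexicon)
  pol <- polarity_label(comp)
  anchors <- emotion_anchors(embedder)
  E <- embed_text(text, embedder)
  labels <- emotion_labels()
  X <- matrix(0, length(labels) + 1L, length(text),
              dimnames = list(c(labels, "neutral"), col$records$id))
  for (j in seq_along(text)) {
    X[seq_along(labels), j] <- vapply(
      labels, function(l) cosine_similarity(E[j, ], anchors[l, ]), 0)
  }
  X["neutral", ] <- comp
  rep_lab <- classify_emotion(text, pol, embedder, mode = mode,
                              compound = comp, anchors = anchors)
  structure(list(X = X, X_rep = rep_lab, compound = comp, polarity = pol,
                 doc_ids = col$records$id, mode = mode),
            class = "emotion_matrix")
}

#' @export
print.emotion_matrix <- function(x, ...) {
  cat(sprintf("<emotion_matrix> %d documents, mode = %s\n",
              length(x$doc_ids), x$mode))
  print(round(100 * table(factor(x$X_rep, c(emotion_labels(), "neutral"))) /
                length(x$X_rep), 1))
  invisible(x)
}
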