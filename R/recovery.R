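#' Match learned topics to planted topic-word distributions
#'
#' Projects the true topic-word distributions onto the fitted
#' vocabulary (words absent from it contribute zero mass), computes
#' all pairwise cosine similarities with the learned dictionary
#' columns, and greedily pairs topics one-to-one in descending cosine
#' order.
#'
#' @param truth_topic_word True `K_true x vocab` topic-word matrix
#'   with word column names (e.g. `ground_truth$topic_word`).
#' @param W Learned `F x k` dictionary with word row names (e.g.
#'   `coef()` of an [onmf()] fit).
#' @return List with `pairs` (data.frame `truth`, `learned`,
#'   `cosine`) and `mean_cosine`, the mean best-match cosine over the
#'   planted topics.
#' @export
match_topics <- function(truth_topic_word, W) {
  words <- rownames(W)
  if (is.null(words) || is.null(colnames(truth_topic_word))) {
    stop("both matrices need word names to be aligned")
  }
  K <- nrow(truth_topic_word)
  k <- ncol(W)
  if (k < K) stop("fewer learned topics than planted topics")
  Tm <- matrix(0, K, length(words))
  common <- intersect(words, colnames(truth_topic_word))
  Tm[, match(common, words)] <- truth_topic_word[, common, drop = FALSE]
  S <- matrix(0, K, k)
  for (i in seq_len(K)) {
    for (j in seq_len(k)) S[i, j] <- cosine_similarity(Tm[i, ], W[, j])
  }
  pairs <- data.frame(truth = integer(0), learned = integer(0), cosine = numeric(0))
  Sm <- S
  for (step in seq_len(K)) {
    ij <- arrayInd(which.max(Sm), dim(Sm))
    pairs <- rbind(pairs, data.frame(truth = ij[1], learned = ij[2],
                                     cosine = S[ij[1], ij[2]]))
    Sm[ij[1], ] <- -Inf
    Sm[, ij[2]] <- -Inf
  }
  pairs <- pairs[order(pairs$truth), ]
  rownames(pairs) <- NULL
  list(pairs = pairs, mean_cosine = mean(pairs$cosine))
}
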