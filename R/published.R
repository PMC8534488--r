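#' Published corpus summary counts
#'
#' The shipped per-topic and per-emotion tweet counts, polarity
#' aggregates and corpus total for the published 60-day COVID-19
#' vaccine discussion corpus (7,948,886 tweets after deduplication).
#'
#' @return data.frame with columns `group`, `key`, `count`.
#' @export
published_summary <- function() {
  utils::read.delim(system.file("extdata", "published_corpus_summary.tsv",
                                package = "tweettrends"),
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' Recompute percentage shares from the published counts
#'
#' Pure arithmetic on the shipped summary counts: each category's
#' percentage of the corpus total, the negative/positive aggregate
#' counts, and the hopefulness count derived from the positive
#' aggregate (the source table prints an inconsistent per-category
#' count for hopefulness, but `positive - joy` pins it down).
#'
#' @return Named list: `total`, per-emotion and per-topic
#'   `*_share_pct`, `negative_count`, `positive_count`,
#'   `hopefulness_count` and aggregate `*_share_pct` values, all
#'   computed (nothing copied from printed percentages).
#' @export
recompute_published_shares <- function() {
  s <- published_summary()
  count_of <- function(group, key) s$count[s$group == group & s$key == key]
  total <- count_of("total", "corpus")
  pct <- function(x) 100 * x / total

  emotions <- s[s$group == "emotion", ]
  out <- stats::setNames(
    as.list(pct(emotions$count)),
    paste0(emotions$key, "_share_pct")
  )
  topics <- s[s$group == "topic", ]
  out[paste0(topics$key, "_share_pct")] <- as.list(pct(topics$count))

  negative_count <- sum(emotions$count[emotions$key %in% negative_emotions()])
  positive_count <- count_of("aggregate", "positive")
  hopefulness_count <- positive_count - count_of("emotion", "joy")
  out$total <- total
  out$negative_count <- negative_count
  out$positive_count <- positive_count
  out$hopefulness_count <- hopefulness_count
  out$hopefulness_share_pct <- pct(hopefulness_count)
  out$negative_share_pct <- pct(negative_count)
  out$positive_share_pct <- pct(positive_count)
  out$neutral_aggregate_share_pct <- pct(count_of("aggregate", "neutral"))
  out
}
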