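test_that("JSONL and CSV reading preserves well-formed records and order", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"id":"a","created_at":"2020-12-16T10:00:00Z","text":"first tweet","lang":"en"}',
    '{"id":"b","created_at":"2020-12-17T11:30:00Z","text":"second tweet"}',
    '{"id":"c","created_at":"2020-12-18T00:00:00Z","text":"third tweet","lang":"fr"}'
  ), tmp)
  col <- read_tweets(tmp)
  expect_s3_class(col, "tweet_collection")
  expect_equal(col$records$id, c("a", "b", "c"))
  expect_equal(col$records$text, c("first tweet", "second tweet", "third tweet"))
  expect_equal(col$records$lang, c("en", NA, "fr"))
  expect_equal(nrow(col$provenance), 0)

  empty <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), empty)
  col0 <- read_tweets(empty)
  expect_equal(nrow(col0$records), 0)
  expect_equal(nrow(col0$provenance), 0)
})

test_that("malformed records abort with the line number, or are skipped on request", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"id":"a","created_at":"2020-12-16T10:00:00Z","text":"ok"}',
    '{"id":"b","created_at":"2020-12-16T10:00:00Z"}'
  ), tmp)
  expect_error(read_tweets(tmp), "line 2")
  expect_warning(col <- read_tweets(tmp, on_error = "skip"), "skipped")
  expect_equal(col$records$id, "a")
  expect_equal(col$provenance$removed, 1L)
})

test_that("write then read round-trips ids, timestamps and texts exactly", {
  col <- make_collection(c("Got my Pfizer shot today", "lovely weather, isn't it?"),
                         times = c(0, 25))
  for (fmt in c("jsonl", "csv")) {
    tmp <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_tweets(col, tmp, format = fmt)
    back <- read_tweets(tmp, format = fmt)
    expect_identical(back$records$id, col$records$id)
    expect_identical(back$records$text, col$records$text)
    expect_equal(back$records$created_at, col$records$created_at)
  }
})

test_that("keyword filtering matches lowercase substrings and hashtags", {
  col <- make_collection(c("Got my Pfizer shot today",
                           "lovely weather today",
                           "#PfizerBioNTech rollout has begun",
                           "corona vaccines arriving soon"))
  out <- filter_by_keywords(col)
  expect_equal(out$records$id, c("d01", "d03", "d04"))
  expect_equal(out$provenance$filter, "keyword")
  expect_equal(out$provenance$removed, 1L)

  expect_error(keyword_filter_spec(character(0)), "nonempty")
  expect_error(keyword_filter_spec(c("Pfizer", "pfizer")), "duplicate")
  expect_equal(keyword_filter_spec(c("A", "b"))$keywords, c("a", "b"))
  # default list has no duplicates after lowercasing
  expect_silent(keyword_filter_spec())
})

test_that("deduplication keeps the earliest record of each normalized text", {
  col <- make_collection(
    c("vaccine works", "RT @alice: vaccine works", "Vaccine   works", "different text"),
    times = c(5, 1, 9, 2))
  out <- deduplicate(col)
  # the retweet at t=1 is earliest in the normalized group
  expect_equal(out$records$id, c("d02", "d04"))
  expect_equal(out$provenance$removed, 2L)

  # tie on created_at broken by smallest id
  tie <- make_collection(c("same text", "same text"), times = c(1, 1),
                         ids = c("z9", "a1"))
  expect_equal(deduplicate(tie)$records$id, "a1")

  # distinct texts both retained
  keep <- make_collection(c("one message", "another message"))
  expect_equal(nrow(deduplicate(keep)$records), 2)
})

test_that("date windowing is inclusive on both endpoints", {
  col <- make_collection(c("on the first day", "after the window"),
                         times = as.POSIXct(c("2020-12-16 00:00:00",
                                              "2021-02-14 00:00:00"), tz = "UTC"))
  out <- filter_window(col, "2020-12-16", "2021-02-13")
  expect_equal(out$records$id, "d01")
  expect_error(filter_window(col, "2021-02-13", "2020-12-16"), "after end")
  empty <- filter_window(make_collection(character(0), times = numeric(0),
                                         ids = character(0)),
                         "2020-12-16", "2021-02-13")
  expect_equal(nrow(empty$records), 0)
})

test_that("language filtering trusts metadata and keeps missing lang by default", {
  col <- make_collection(c("in english", "en francais", "no metadata"),
                         lang = c("en", "fr", NA))
  expect_equal(filter_language(col)$records$id, c("d01", "d03"))
  expect_equal(filter_language(col, drop_missing = TRUE)$records$id, "d01")
})

test_that("record-local filters commute and provenance counts are exact", {
  set.seed(42)
  texts <- c("pfizer dose one", "moderna here", "nothing relevant",
             "vaccine news", "weather report", "astrazeneca update")
  col <- make_collection(texts,
                         times = as.POSIXct("2020-12-10", tz = "UTC") +
                           (seq_along(texts) * 3) * 86400,
                         lang = c("en", "fr", "en", "en", NA, "en"))
  a <- filter_language(filter_window(filter_by_keywords(col),
                                     "2020-12-16", "2021-02-13"))
  b <- filter_by_keywords(filter_language(filter_window(col,
                                                        "2020-12-16", "2021-02-13")))
  expect_setequal(a$records$id, b$records$id)
  # input size = output size + removals, along both orders
  expect_equal(nrow(col$records), nrow(a$records) + sum(a$provenance$removed))
  expect_equal(nrow(col$records), nrow(b$records) + sum(b$provenance$removed))
})
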