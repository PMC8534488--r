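#' Construct a tweet collection
#'
#' A tweet collection holds tweet-like short-text records (id, UTC
#' timestamp, text, optional language code) together with a provenance
#' table recording every filter applied to it and how many records each
#' filter removed.
#'
#' @param records data.frame with columns `id` (character, unique,
#'   nonempty), `created_at` (POSIXct in UTC, or ISO-8601 strings),
#'   `text` (character, nonempty) and optionally `lang` (character,
#'   `NA` allowed).
#' @param provenance data.frame with columns `filter` (character) and
#'   `removed` (integer); empty by default.
#' @return An object of class `tweet_collection`.
#' @export
tweet_collection <- function(records, provenance = NULL) {
  stopifnot(is.data.frame(records))
  required <- c("id", "created_at", "text")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("records is missing required column(s): ", paste(missing, collapse = ", "))
  }
  records$id <- as.character(records$id)
  records$text <- as.character(records$text)
  if (!inherits(records$created_at, "POSIXct")) {
    records$created_at <- parse_utc(records$created_at)
  }
  attr(records$created_at, "tzone") <- "UTC"
  if (!"lang" %in% names(records)) records$lang <- NA_character_
  records$lang <- as.character(records$lang)
  if (nrow(records)) {
    if (anyNA(records$id) || any(!nzchar(records$id))) {
      stop("all record ids must be nonempty")
    }
    if (anyDuplicated(records$id)) {
      stop("record ids must be unique; duplicated: ",
           paste(utils::head(unique(records$id[duplicated(records$id)]), 5), collapse = ", "))
    }
    if (anyNA(records$created_at)) stop("unparseable created_at timestamp(s)")
    if (anyNA(records$text) || any(!nzchar(records$text))) {
      stop("all record texts must be nonempty")
    }
  }
  if (is.null(provenance)) {
    provenance <- data.frame(filter = character(), removed = integer(),
                             stringsAsFactors = FALSE)
  }
  rownames(records) <- NULL
  structure(list(records = records[c("id", "created_at", "text", "lang")],
                 provenance = provenance),
            class = "tweet_collection")
}

# ISO-8601 parser tolerant of "Z" suffixes and space separators; all UTC.
parse_utc <- function(x) {
  x <- sub("Z$", "", sub("\\+00:?00$", "", as.character(x)))
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  out
}

#' @export
print.tweet_collection <- function(x, ...) {
  cat(sprintf("<tweet_collection> %d records", nrow(x$records)))
  if (nrow(x$records)) {
    rng <- range(x$records$created_at)
    cat(sprintf(", %s .. %s UTC", format(rng[1], "%Y-%m-%d"), format(rng[2], "%Y-%m-%d")))
  }
  cat("\n")
  if (nrow(x$provenance)) {
    for (i in seq_len(nrow(x$provenance))) {
      cat(sprintf("  filter %-18s removed %d\n",
                  x$provenance$filter[i], x$provenance$removed[i]))
    }
  }
  invisible(x)
}

#' @export
length.tweet_collection <- function(x) nrow(x$records)

# Append one provenance row, checking the removal count is exact.
add_provenance <- function(col, name, n_before, n_after) {
  stopifnot(n_after <= n_before)
  col$provenance <- rbind(
    col$provenance,
    data.frame(filter = name, removed = n_before - n_after, stringsAsFactors = FALSE)
  )
  col
}

#' Read tweet-like records from JSONL or CSV
#'
#' Each record must carry `id`, `created_at` (ISO-8601 UTC) and `text`;
#' `lang` is optional. JSONL holds one JSON object per line; CSV is
#' UTF-8 with a header row and RFC-4180 quoting.
#'
#' @param path Input file.
#' @param format `"jsonl"` or `"csv"`; inferred from the extension when
#'   missing.
#' @param on_error `"abort"` (default) stops at the first malformed
#'   record, naming its line; `"skip"` drops malformed records with a
#'   warning and counts them in provenance.
#' @return A [tweet_collection()] preserving input order.
#' @export
read_tweets <- function(path, format = c("auto", "jsonl", "csv"),
                        on_error = c("abort", "skip")) {
  format <- match.arg(format)
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    rows <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
    lineno <- seq_len(nrow(df)) + 1L
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    keep <- nzchar(trimws(lines))
    rows <- lapply(lines[keep], function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
    lineno <- which(keep)
  }
  required <- c("id", "created_at", "text")
  ok <- vapply(rows, function(r) {
    all(required %in% names(r)) &&
      all(vapply(r[required], function(v) length(v) == 1 && !is.na(v) && nzchar(as.character(v)), TRUE))
  }, TRUE)
  if (any(!ok)) {
    bad <- lineno[!ok]
    if (on_error == "abort") {
      stop("malformed record (missing/empty id, created_at or text) at line ",
           paste(utils::head(bad, 5), collapse = ", "), " of ", path)
    }
    warning(sum(!ok), " malformed record(s) skipped while reading ", path)
  }
  rows <- rows[ok]
  df <- data.frame(
    id = vapply(rows, function(r) as.character(r$id), ""),
    created_at = vapply(rows, function(r) as.character(r$created_at), ""),
    text = vapply(rows, function(r) as.character(r$text), ""),
    lang = vapply(rows, function(r) {
      if (!is.null(r$lang) && !is.na(r$lang)) as.character(r$lang) else NA_character_
    }, ""),
    stringsAsFactors = FALSE
  )
  col <- tweet_collection(df)
  if (any(!ok)) col <- add_provenance(col, "read_skip_malformed", length(ok), sum(ok))
  col
}

#' Write a tweet collection to JSONL or CSV
#'
#' Inverse of [read_tweets()]: a write followed by a read reproduces
#' ids, timestamps and texts exactly.
#'
#' @param col A [tweet_collection()].
#' @param path Output file.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_tweets <- function(col, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(col, "tweet_collection"))
  df <- col$records
  df$created_at <- format(df$created_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      r <- as.list(df[i, , drop = FALSE])
      if (is.na(r$lang)) r$lang <- NULL
      jsonlite::toJSON(r, auto_unbox = TRUE)
    }, "")
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Default vaccine keyword list
#'
#' The 21 unique lowercased keywords, phrases and hashtags used to
#' retain vaccine-related tweets (brand names, generic vaccine terms
#' and their hashtag forms).
#'
#' @return Character vector of keywords.
#' @export
default_keywords <- function() {
  readLines(system.file("extdata", "vaccine_keywords.txt", package = "tweettrends"),
            encoding = "UTF-8")
}

#' Keyword filter specification
#'
#' Validates and lowercases a keyword list. Plain words and multiword
#' phrases are matched as contiguous lowercase substrings; entries
#' prefixed with `#` are matched as literal hashtag substrings.
#'
#' @param keywords Character vector; defaults to [default_keywords()].
#' @return Object of class `keyword_filter_spec`.
#' @export
keyword_filter_spec <- function(keywords = default_keywords()) {
  keywords <- tolower(trimws(keywords))
  keywords <- keywords[nzchar(keywords)]
  if (!length(keywords)) stop("keyword list must be nonempty")
  if (anyDuplicated(keywords)) {
    stop("duplicate keywords after lowercasing: ",
         paste(unique(keywords[duplicated(keywords)]), collapse = ", "))
  }
  structure(list(keywords = keywords), class = "keyword_filter_spec")
}

#' Keep records containing at least one keyword
#'
#' @param col A [tweet_collection()].
#' @param spec A [keyword_filter_spec()] (or character vector of
#'   keywords).
#' @return Filtered collection; the provenance table gains a
#'   `keyword` row.
#' @export
filter_by_keywords <- function(col, spec = keyword_filter_spec()) {
  stopifnot(inherits(col, "tweet_collection"))
  if (!inherits(spec, "keyword_filter_spec")) spec <- keyword_filter_spec(spec)
  txt <- tolower(col$records$text)
  keep <- rep(FALSE, length(txt))
  for (kw in spec$keywords) {
    keep <- keep | grepl(kw, txt, fixed = TRUE)
    if (all(keep)) break
  }
  out <- col
  out$records <- col$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  add_provenance(out, "keyword", length(keep), sum(keep))
}

# Text normalization used only for duplicate detection: strip a leading
# retweet prefix, collapse whitespace, casefold.
normalize_for_dedup <- function(text) {
  x <- sub("^[Rr][Tt] @[A-Za-z0-9_]+:\\s*", "", text)
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}

#' Remove duplicated content (retweets and exact duplicates)
#'
#' Texts are normalized (leading `RT @handle:` prefix removed,
#' whitespace collapsed, casefolded) and each group of identical
#' normalized texts is reduced to its earliest record by `created_at`,
#' ties broken by smallest id.
#'
#' @param col A [tweet_collection()].
#' @return Deduplicated collection, in original record order.
#' @export
deduplicate <- function(col) {
  stopifnot(inherits(col, "tweet_collection"))
  df <- col$records
  n <- nrow(df)
  if (n == 0) return(add_provenance(col, "dedup", 0L, 0L))
  key <- normalize_for_dedup(df$text)
  ord <- order(key, df$created_at, df$id)
  keep_sorted <- !duplicated(key[ord])
  keep <- sort(ord[keep_sorted])
  out <- col
  out$records <- df[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  add_provenance(out, "dedup", n, length(keep))
}

#' Restrict a collection to a calendar-date window
#'
#' Retains records whose UTC calendar date lies in `[start, end]`,
#' both endpoints inclusive.
#'
#' @param col A [tweet_collection()].
#' @param start,end `Date` (or coercible); `start <= end` required.
#' @return Filtered collection.
#' @export
filter_window <- function(col, start, end) {
  stopifnot(inherits(col, "tweet_collection"))
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("unparseable window endpoint")
  if (start > end) stop("window start is after end")
  d <- as.Date(col$records$created_at, tz = "UTC")
  keep <- d >= start & d <= end
  out <- col
  out$records <- col$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  add_provenance(out, "window", length(keep), sum(keep))
}

#' Filter by language metadata
#'
#' Trusts the `lang` metadata field; no language identification model
#' is applied. Records with missing `lang` are retained by default.
#'
#' @param col A [tweet_collection()].
#' @param lang Two-letter language code, default `"en"`.
#' @param drop_missing Drop records whose `lang` is missing? Default
#'   `FALSE`.
#' @return Filtered collection.
#' @export
filter_language <- function(col, lang = "en", drop_missing = FALSE) {
  stopifnot(inherits(col, "tweet_collection"))
  l <- col$records$lang
  keep <- ifelse(is.na(l), !drop_missing, l == lang)
  out <- col
  out$records <- col$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  add_provenance(out, "language", length(keep), sum(keep))
}
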