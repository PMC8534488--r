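#' Merge topic and emotion assignments
#'
#' Joins the representative topics, representative emotions and
#' timestamps on the unique document ids. The three inputs must cover
#' exactly the same id set.
#'
#' @param topics A [assign_topics()] result.
#' @param emotions An [emotion_matrix()] result.
#' @param col The [tweet_collection()] the assignments were computed
#'   from (supplies the timestamps).
#' @return Object of class `topic_sentiment_table`: data.frame with
#'   columns `doc_id`, `created_at`, `topic` (integer, `NA` =
#'   unassigned) and `emotion`, plus attribute `k`.
#' @export
merge_topic_emotion <- function(topics, emotions, col) {
  stopifnot(inherits(topics, "topic_assignment"),
            inherits(emotions, "emotion_matrix"),
            inherits(col, "tweet_collection"))
  ids <- col$records$id
  if (!length(ids)) stop("empty collection")
  miss_t <- c(setdiff(ids, topics$doc_ids), setdiff(topics$doc_ids, ids))
  miss_e <- c(setdiff(ids, emotions$doc_ids), setdiff(emotions$doc_ids, ids))
  if (length(miss_t) || length(miss_e)) {
    stop("document id mismatch between inputs: ",
         paste(utils::head(unique(c(miss_t, miss_e)), 5), collapse = ", "))
  }
  out <- data.frame(
    doc_id = ids,
    created_at = col$records$created_at,
    topic = topics$topic[match(ids, topics$doc_ids)],
    emotion = emotions$X_rep[match(ids, emotions$doc_ids)],
    stringsAsFactors = FALSE
  )
  attr(out, "k") <- topics$k
  class(out) <- c("topic_sentiment_table", "data.frame")
  out
}

# One trend_series: ordered calendar days + values. Zero-volume days
# yield NA proportions (not zeros): silence carries no sentiment.
trend_series <- function(dates, values, kind = c("proportion", "count"),
                         smoothing = "none") {
  kind <- match.arg(kind)
  stopifnot(length(dates) == length(values), !is.unsorted(dates, strictly = TRUE))
  structure(list(dates = as.Date(dates), values = as.numeric(values),
                 kind = kind, smoothing = smoothing),
            class = "trend_series")
}

#' @export
print.trend_series <- function(x, ...) {
  cat(sprintf("<trend_series> %s, %d days (%s .. %s), smoothing = %s\n",
              x$kind, length(x$dates), min(x$dates), max(x$dates), x$smoothing))
  invisible(x)
}

#' @export
plot.trend_series <- function(x, ...) {
  graphics::plot(x$dates, x$values, type = "l", xlab = "date", ylab = x$kind, ...)
  invisible(x)
}

table_dates <- function(table) {
  d <- as.Date(table$created_at, tz = "UTC")
  seq(min(d), max(d), by = "day")
}

#' Daily share of one topic
#'
#' For every calendar day in the table's span, the fraction of that
#' day's assigned documents whose representative topic is `topic`.
#' Days without assigned documents yield `NA`.
#'
#' @param table A [merge_topic_emotion()] result.
#' @param topic Topic index.
#' @return A proportion `trend_series`.
#' @export
daily_topic_series <- function(table, topic) {
  stopifnot(inherits(table, "topic_sentiment_table"), nrow(table) > 0)
  day <- as.Date(table$created_at, tz = "UTC")
  days <- table_dates(table)
  assigned <- !is.na(table$topic)
  denom <- tapply(assigned, day, sum)[as.character(days)]
  num <- tapply(assigned & table$topic == topic, day, sum)[as.character(days)]
  denom[is.na(denom)] <- 0
  num[is.na(num)] <- 0
  vals <- ifelse(denom > 0, num / denom, NA_real_)
  trend_series(days, vals, "proportion")
}

#' Daily emotion shares
#'
#' Per calendar day, the proportion of each of the six labels (five
#' emotions plus neutral) among the documents in scope; the six
#' proportions sum to 1 on every day with nonzero volume, and
#' zero-volume days are emitted as missing.
#'
#' @param table A [merge_topic_emotion()] result.
#' @param scope `NULL` for the whole corpus or a topic index to
#'   restrict to one topic's documents.
#' @return Named list of proportion `trend_series`, one per label.
#' @export
daily_emotion_series <- function(table, scope = NULL) {
  stopifnot(inherits(table, "topic_sentiment_table"), nrow(table) > 0)
  days <- table_dates(table)
  sub <- if (is.null(scope)) table else table[!is.na(table$topic) & table$topic == scope, ]
  day <- as.Date(sub$created_at, tz = "UTC")
  labels <- c(emotion_labels(), "neutral")
  denom <- tapply(rep(1L, nrow(sub)), day, sum)[as.character(days)]
  denom[is.na(denom)] <- 0
  out <- lapply(labels, function(l) {
    num <- tapply(sub$emotion == l, day, sum)[as.character(days)]
    num[is.na(num)] <- 0
    trend_series(days, ifelse(denom > 0, num / denom, NA_real_), "proportion")
  })
  stats::setNames(out, labels)
}

#' Daily volume in scope
#'
#' @param table A [merge_topic_emotion()] result.
#' @param scope `NULL` or topic index.
#' @return A count `trend_series`.
#' @export
daily_volume_series <- function(table, scope = NULL) {
  stopifnot(inherits(table, "topic_sentiment_table"), nrow(table) > 0)
  days <- table_dates(table)
  sub <- if (is.null(scope)) table else table[!is.na(table$topic) & table$topic == scope, ]
  day <- as.Date(sub$created_at, tz = "UTC")
  num <- tapply(rep(1L, nrow(sub)), day, sum)[as.character(days)]
  num[is.na(num)] <- 0
  trend_series(days, num, "count")
}

#' Weekly (7-day centered rolling mean) smoothing
#'
#' Centered 7-day rolling mean with shrinking windows at the series
#' boundaries; missing values inside a window are ignored, and a
#' window with no observed value yields `NA`.
#'
#' @param series A `trend_series`.
#' @return A `trend_series` with `smoothing = "rolling7"`.
#' @export
weekly_smooth <- function(series) {
  stopifnot(inherits(series, "trend_series"))
  v <- series$values
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    win <- v[max(1L, i - 3L):min(n, i + 3L)]
    out[i] <- if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }
  trend_series(series$dates, out, series$kind, smoothing = "rolling7")
}

# MacKinnon (1994/2010) approximate asymptotic p-value for the ADF
# tau statistic, constant-only regression, one I(1) series.
mackinnon_pvalue <- function(stat) {
  if (stat > 2.74) return(1)
  if (stat < -18.83) return(0)
  z <- if (stat <= -1.61) {
    2.1659 + 1.4412 * stat + 0.038269 * stat^2
  } else {
    1.7339 + 0.93202 * stat - 0.12745 * stat^2 - 0.010368 * stat^3
  }
  stats::pnorm(z)
}

#' Augmented Dickey-Fuller stationarity test
#'
#' Fits the augmented Dickey-Fuller regression with a constant term
#' (no deterministic trend),
#' `diff(y)_t = a + rho * y_(t-1) + sum_i phi_i diff(y)_(t-i) + e_t`,
#' selecting the lag order by AIC over `0..max_lag` on a common
#' estimation sample, then refits at the chosen order on the full
#' usable sample. The test statistic is the t statistic of `rho`;
#' p-values use the MacKinnon approximate asymptotic response surface.
#' Rejection of the unit-root null (`p < alpha`) is reported as
#' stationarity.
#'
#' @param series A `trend_series` or numeric vector; at least 10
#'   non-missing values, non-constant, and internally complete.
#' @param alpha Significance level (default 0.05).
#' @param max_lag Maximum augmentation lag; default
#'   `floor((n - 1)^(1/3))`.
#' @return Object of class `adf_test`: list with `statistic`,
#'   `p_value`, `n_lags`, `n`, `alpha`, `stationary`.
#' @export
adf_test <- function(series, alpha = 0.05, max_lag = NULL) {
  x <- if (inherits(series, "trend_series")) series$values else as.numeric(series)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 10) stop("series too short for the ADF test (need >= 10 points)")
  if (stats::sd(x) == 0) stop("zero variance: constant series")
  if (is.null(max_lag)) max_lag <- floor((n - 1)^(1 / 3))
  max_lag <- max(0L, min(as.integer(max_lag), n - 3L))
  d <- diff(x)

  fit_adf <- function(p, trim) {
    # response d_t for t = trim+1 .. n-1; level x_t; lagged diffs
    idx <- (trim + 1L):(n - 1L)
    X <- cbind(level = x[idx])
    if (p > 0) for (j in seq_len(p)) X <- cbind(X, d[idx - j])
    colnames(X) <- c("level", if (p > 0) paste0("dlag", seq_len(p)))
    stats::lm(d[idx] ~ X)
  }
  # lag selection on the common sample trimmed at max_lag
  aics <- vapply(0:max_lag, function(p) {
    fit <- fit_adf(p, max_lag)
    rss <- sum(stats::residuals(fit)^2)
    nn <- length(stats::residuals(fit))
    nn * log(rss / nn) + 2 * (p + 2)
  }, 0)
  p_best <- (0:max_lag)[which.min(aics)]
  fit <- fit_adf(p_best, p_best)
  ct <- summary(fit)$coefficients
  stat <- ct[2, "t value"]  # the lagged-level term (first regressor)
  pval <- mackinnon_pvalue(stat)
  structure(list(statistic = unname(stat), p_value = pval,
                 n_lags = p_best, n = n, alpha = alpha,
                 stationary = pval < alpha),
            class = "adf_test")
}

#' @export
print.adf_test <- function(x, ...) {
  cat("Augmented Dickey-Fuller test (constant, no trend)\n")
  cat(sprintf("  tau = %.4f, lag order = %d, n = %d\n", x$statistic, x$n_lags, x$n))
  cat(sprintf("  p-value = %.4f -> %s at alpha = %g\n", x$p_value,
              if (x$stationary) "stationary" else "non-stationary", x$alpha))
  invisible(x)
}

#' Tidy trend table for a set of series
#'
#' @param series_list Named list of `trend_series`.
#' @param scope Scope label recorded in the output.
#' @return data.frame with columns `date`, `scope`, `key`, `value`,
#'   `smoothing`.
#' @export
trend_frame <- function(series_list, scope = "overall") {
  do.call(rbind, lapply(names(series_list), function(nm) {
    s <- series_list[[nm]]
    data.frame(date = format(s$dates), scope = scope, key = nm,
               value = s$values, smoothing = s$smoothing,
               stringsAsFactors = FALSE)
  }))
}
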