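#' Pipeline configuration
#'
#' Bundles every stage setting of the corpus-to-trend-report pipeline.
#' Defaults mirror the production analysis: 50 topics with batch size
#' 2000, the shipped vaccine keyword list, the 60-day window
#' 2020-12-16..2021-02-13, English-only, polarity thresholds at
#' `± 0.05` and ADF significance 0.05. For synthetic runs see
#' [preset_pipeline_config()].
#'
#' @param workdir Directory all stage artifacts are written to.
#' @param input Optional external corpus file (JSONL/CSV) for the
#'   ingest stage; when `NULL`, the generated `corpus.jsonl` in
#'   `workdir` is ingested.
#' @param preset Synthetic preset name for the generate stage
#'   (see [corpus_presets()]), or `NULL`.
#' @param synthetic Explicit [synthetic_config()] overriding `preset`.
#' @param keywords Keyword list (or [keyword_filter_spec()]);
#'   `NULL` disables keyword filtering.
#' @param window `c(start, end)` dates; `NULL` disables windowing.
#' @param language Language code to keep; `NULL` disables the filter.
#' @param min_df,max_df_frac,tfidf_scheme Vocabulary and encoding
#'   settings (see [build_vocabulary()], [tfidf_matrix()]).
#' @param k,batch_size,inner_iters,passes ONMF settings (see
#'   [onmf()]).
#' @param lexicon Path to a sentiment lexicon TSV; `NULL` uses the
#'   generated planted lexicons when present, else the bundled one.
#' @param embedder `"toy"` or a registered embedder name.
#' @param mode Emotion mode, `"gated"` or `"global"`.
#' @param alpha ADF significance level.
#' @param seed Seed propagated to every stochastic stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(workdir, input = NULL, preset = NULL,
                            synthetic = NULL,
                            keywords = default_keywords(),
                            window = c("2020-12-16", "2021-02-13"),
                            language = "en",
                            min_df = 2L, max_df_frac = 0.95,
                            tfidf_scheme = "classic",
                            k = 50L, batch_size = 2000L,
                            inner_iters = 100L, passes = 1L,
                            lexicon = NULL, embedder = "toy",
                            mode = "gated", alpha = 0.05, seed = 1L) {
  structure(list(workdir = workdir, input = input, preset = preset,
                 synthetic = synthetic, keywords = keywords, window = window,
                 language = language, min_df = as.integer(min_df),
                 max_df_frac = max_df_frac, tfidf_scheme = tfidf_scheme,
                 k = as.integer(k), batch_size = as.integer(batch_size),
                 inner_iters = as.integer(inner_iters),
                 passes = as.integer(passes), lexicon = lexicon,
                 embedder = embedder, mode = mode, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Pipeline configuration for a synthetic preset
#'
#' A [pipeline_config()] wired for an end-to-end run on a synthetic
#' corpus: no keyword/window/language filtering (the generator already
#' controls those), a topic count of `k` (default 8, leaving headroom
#' above the planted 5 so near-empty topics exercise the ratio
#' filter), and the planted lexicons driving polarity and the toy
#' embedder.
#'
#' @param preset Preset name (see [corpus_presets()]).
#' @param workdir Artifact directory.
#' @param k Fitted topic count (default 8).
#' @param seed Seed for every stochastic stage.
#' @param ... Further overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
preset_pipeline_config <- function(preset, workdir, k = 8L, seed = 1L, ...) {
  pipeline_config(workdir = workdir, preset = preset, keywords = NULL,
                  window = NULL, language = NULL, k = k,
                  batch_size = 500L, seed = seed, ...)
}

# Hash of the scientific settings (paths excluded so relocating a
# workdir does not change it).
config_hash <- function(config) {
  core <- config[setdiff(names(config), c("workdir", "input", "lexicon"))]
  if (inherits(core$synthetic, "synthetic_config")) {
    core$synthetic <- unclass(core$synthetic)
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(core, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

artifact <- function(config, name) file.path(config$workdir, name)

require_artifact <- function(config, name, stage) {
  p <- artifact(config, name)
  if (!file.exists(p)) {
    stop("missing artifact ", name, ": run stage '", stage, "' first")
  }
  p
}

write_stage_tsv <- function(df, path, hash) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s", hash), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_stage_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

pipeline_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
  invisible(NULL)
}

# Resolve the sentiment lexicon + embedder for a config: an explicit
# lexicon path wins; otherwise planted lexicons emitted by the
# generate stage; otherwise the bundled mini lexicon.
resolve_sentiment <- function(config) {
  planted <- artifact(config, "truth_lexicons.tsv")
  if (!is.null(config$lexicon)) {
    lex <- read_lexicon(config$lexicon)
    lexicons <- default_emotion_lexicons()
  } else if (file.exists(planted)) {
    df <- read_stage_tsv(planted)
    lexicons <- lapply(split(df, df$emotion), function(g) {
      stats::setNames(g$valence, g$token)
    })
    lexicons <- lexicons[intersect(emotion_labels(), names(lexicons))]
    lex <- sentiment_lexicon(unlist(unname(lexicons)))
  } else {
    lex <- default_lexicon()
    lexicons <- default_emotion_lexicons()
  }
  emb <- if (identical(config$embedder, "toy")) toy_embedder(lexicons)
         else get_embedder(config$embedder)
  list(lexicon = lex, embedder = emb)
}

#' Run one pipeline stage
#'
#' Stages: `generate` (synthetic corpus), `ingest` (read + filter +
#' dedup), `preprocess` (tokenize + vocabulary + tf-idf), `topics`
#' (ONMF fit, loadings, assignment, ratio filter, top words),
#' `sentiment` (polarity + gated emotions), `trends` (daily/weekly
#' series + ADF), `report` (markdown summary). Each stage reads its
#' upstream artifacts from `config$workdir` (erroring with the name of
#' the stage to run first when they are missing), writes its outputs
#' under fixed file names with the configuration hash in every header,
#' and is idempotent given identical inputs and seed.
#'
#' @param stage One of the stage names above.
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages? Default `TRUE`.
#' @return Character vector of the artifact paths written, invisibly.
#' @export
run_stage <- function(stage = c("generate", "ingest", "preprocess", "topics",
                                "sentiment", "trends", "report"),
                      config, quiet = TRUE) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$workdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  out <- switch(stage,
    generate = stage_generate(config, hash, quiet),
    ingest = stage_ingest(config, hash, quiet),
    preprocess = stage_preprocess(config, hash, quiet),
    topics = stage_topics(config, hash, quiet),
    sentiment = stage_sentiment(config, hash, quiet),
    trends = stage_trends(config, hash, quiet),
    report = stage_report(config, hash, quiet)
  )
  invisible(out)
}

#' Run a sequence of pipeline stages
#'
#' @param config A [pipeline_config()].
#' @param stages Stage names in order; the default runs everything
#'   (including generation when a preset or synthetic config is set).
#' @param quiet Suppress progress messages?
#' @return Named list of artifact path vectors, invisibly.
#' @export
run_pipeline <- function(config, stages = NULL, quiet = TRUE) {
  if (is.null(stages)) {
    stages <- c(if (!is.null(config$preset) || !is.null(config$synthetic)) "generate",
                "ingest", "preprocess", "topics", "sentiment", "trends", "report")
  }
  out <- lapply(stages, run_stage, config = config, quiet = quiet)
  invisible(stats::setNames(out, stages))
}

stage_generate <- function(config, hash, quiet) {
  cfg <- config$synthetic
  if (is.null(cfg)) {
    if (is.null(config$preset)) stop("generate stage needs a preset or synthetic config")
    cfg <- corpus_presets(config$preset)
  }
  cfg$seed <- config$seed
  gen <- generate_corpus(cfg)
  p_corpus <- artifact(config, "corpus.jsonl")
  write_tweets(gen$collection, p_corpus)
  truth_paths <- write_ground_truth(gen$truth, artifact(config, "truth"))
  pipeline_log(quiet, "generate: %d documents over %d days",
               nrow(gen$collection$records), cfg$n_days)
  c(p_corpus, truth_paths)
}

stage_ingest <- function(config, hash, quiet) {
  src <- if (!is.null(config$input)) {
    if (!file.exists(config$input)) stop("input corpus not found: ", config$input)
    config$input
  } else {
    require_artifact(config, "corpus.jsonl", "generate")
  }
  col <- read_tweets(src)
  if (!is.null(config$keywords)) col <- filter_by_keywords(col, keyword_filter_spec(config$keywords))
  if (!is.null(config$window)) col <- filter_window(col, config$window[1], config$window[2])
  if (!is.null(config$language)) col <- filter_language(col, config$language)
  col <- deduplicate(col)
  p1 <- artifact(config, "corpus_filtered.jsonl")
  write_tweets(col, p1)
  p2 <- write_stage_tsv(col$provenance, artifact(config, "provenance.tsv"), hash)
  pipeline_log(quiet, "ingest: %d records retained", nrow(col$records))
  c(p1, p2)
}

stage_preprocess <- function(config, hash, quiet) {
  src <- require_artifact(config, "corpus_filtered.jsonl", "ingest")
  col <- read_tweets(src)
  docs <- tokenize(col$records$text)
  vocab <- build_vocabulary(docs, min_df = config$min_df,
                            max_df_frac = config$max_df_frac)
  V <- tfidf_matrix(docs, vocab, scheme = config$tfidf_scheme,
                    doc_ids = col$records$id)
  p1 <- artifact(config, "vocab.tsv"); write_vocabulary(vocab, p1)
  p2 <- artifact(config, "V.mtx"); write_tfidf(V, p2)
  pipeline_log(quiet, "preprocess: %d words x %d documents", nrow(V$values), ncol(V$values))
  c(p1, p2)
}

stage_topics <- function(config, hash, quiet) {
  vocab <- read_vocabulary(require_artifact(config, "vocab.tsv", "preprocess"))
  V <- read_tfidf(require_artifact(config, "V.mtx", "preprocess"), vocab)
  model <- onmf(V, k = config$k, batch_size = config$batch_size,
                inner_iters = config$inner_iters, passes = config$passes,
                seed = config$seed)
  H <- predict(model, V)
  assign <- assign_topics(H)
  ratios <- topic_ratios(assign)
  retained <- filter_topics(ratios)
  p_w <- artifact(config, "W.mtx")
  Matrix::writeMM(methods::as(Matrix::Matrix(model$W, sparse = TRUE), "CsparseMatrix"), p_w)
  writeLines(jsonlite::toJSON(list(config_hash = hash, k = config$k,
                                   batch_size = config$batch_size,
                                   seed = config$seed,
                                   words = rownames(model$W)),
                              auto_unbox = TRUE),
             paste0(p_w, ".json"))
  p_t <- write_stage_tsv(
    data.frame(doc_id = assign$doc_ids, topic = assign$topic),
    artifact(config, "topics.tsv"), hash)
  p_r <- write_stage_tsv(
    data.frame(topic = seq_along(ratios), ratio = ratios,
               retained = seq_along(ratios) %in% retained),
    artifact(config, "topic_ratios.tsv"), hash)
  tw <- do.call(rbind, lapply(retained, function(t) {
    cbind(topic = t, top_words(model, t, 10))
  }))
  p_tw <- write_stage_tsv(tw, artifact(config, "top_words.tsv"), hash)
  pipeline_log(quiet, "topics: %d of %d topics retained", length(retained), config$k)
  c(p_w, p_t, p_r, p_tw)
}

stage_sentiment <- function(config, hash, quiet) {
  src <- require_artifact(config, "corpus_filtered.jsonl", "ingest")
  col <- read_tweets(src)
  parts <- resolve_sentiment(config)
  em <- emotion_matrix(col, lexicon = parts$lexicon,
                       embedder = parts$embedder, mode = config$mode)
  p <- write_stage_tsv(
    data.frame(doc_id = em$doc_ids, compound = em$compound,
               polarity = em$polarity, emotion = em$X_rep),
    artifact(config, "sentiment.tsv"), hash)
  pipeline_log(quiet, "sentiment: %d documents classified", length(em$doc_ids))
  p
}

stage_trends <- function(config, hash, quiet) {
  col <- read_tweets(require_artifact(config, "corpus_filtered.jsonl", "ingest"))
  topics_df <- read_stage_tsv(require_artifact(config, "topics.tsv", "topics"))
  ratios_df <- read_stage_tsv(require_artifact(config, "topic_ratios.tsv", "topics"))
  sent_df <- read_stage_tsv(require_artifact(config, "sentiment.tsv", "sentiment"))
  assign <- structure(list(topic = as.integer(topics_df$topic),
                           doc_ids = as.character(topics_df$doc_id),
                           k = nrow(ratios_df)),
                      class = "topic_assignment")
  em <- structure(list(X_rep = sent_df$emotion,
                       doc_ids = as.character(sent_df$doc_id)),
                  class = "emotion_matrix")
  tab <- merge_topic_emotion(assign, em, col)
  retained <- ratios_df$topic[ratios_df$retained]

  frames <- list()
  emo <- daily_emotion_series(tab)
  frames[[length(frames) + 1]] <- trend_frame(emo, "overall")
  frames[[length(frames) + 1]] <- trend_frame(lapply(emo, weekly_smooth), "overall")
  for (t in retained) {
    ts_t <- list(daily_topic_series(tab, t))
    names(ts_t) <- sprintf("topic%02d", t)
    frames[[length(frames) + 1]] <- trend_frame(ts_t, "topics")
    frames[[length(frames) + 1]] <- trend_frame(lapply(ts_t, weekly_smooth), "topics")
    emo_t <- daily_emotion_series(tab, scope = t)
    frames[[length(frames) + 1]] <- trend_frame(emo_t, sprintf("topic%02d", t))
  }
  p1 <- write_stage_tsv(do.call(rbind, frames), artifact(config, "trends.tsv"), hash)
  adf <- lapply(names(emo), function(l) {
    res <- tryCatch(adf_test(emo[[l]], alpha = config$alpha),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(series = l, statistic = res$statistic, p_value = res$p_value,
               lags = res$n_lags, stationary = res$stationary)
  })
  p2 <- write_stage_tsv(do.call(rbind, adf), artifact(config, "adf.tsv"), hash)
  pipeline_log(quiet, "trends: %d retained topics, %d emotion series tested",
               length(retained), sum(!vapply(adf, is.null, TRUE)))
  c(p1, p2)
}

stage_report <- function(config, hash, quiet) {
  prov <- read_stage_tsv(require_artifact(config, "provenance.tsv", "ingest"))
  ratios <- read_stage_tsv(require_artifact(config, "topic_ratios.tsv", "topics"))
  tw <- read_stage_tsv(require_artifact(config, "top_words.tsv", "topics"))
  sent <- read_stage_tsv(require_artifact(config, "sentiment.tsv", "sentiment"))
  adf <- read_stage_tsv(require_artifact(config, "adf.tsv", "trends"))
  lines <- c(
    "# Topic and emotion trend report",
    sprintf("config_hash: %s", hash),
    "",
    "## Corpus filters",
    sprintf("- %s: removed %d", prov$filter, prov$removed),
    "",
    "## Retained topics (ratio >= 1/k)",
    sprintf("- topic %d: ratio %.4f, top words: %s",
            ratios$topic[ratios$retained],
            ratios$ratio[ratios$retained],
            vapply(ratios$topic[ratios$retained], function(t) {
              paste(utils::head(tw$word[tw$topic == t], 5), collapse = " ")
            }, "")),
    "",
    "## Emotion shares",
    sprintf("- %s: %.1f%%",
            names(table(sent$emotion)),
            100 * as.numeric(table(sent$emotion)) / nrow(sent)),
    "",
    "## Stationarity (augmented Dickey-Fuller, constant only)",
    sprintf("- %s: tau = %.3f, p = %.4f, lags = %d -> %s",
            adf$series, adf$statistic, adf$p_value, adf$lags,
            ifelse(adf$stationary, "stationary", "non-stationary"))
  )
  p <- artifact(config, "report.md")
  writeLines(lines, p)
  pipeline_log(quiet, "report: written to %s", p)
  p
}
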