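#' Default English stopword list
#'
#' @return Character vector of stopwords (shipped as a plain-text data
#'   file, one word per line).
#' @export
default_stopwords <- function() {
  readLines(system.file("extdata", "stopwords_en.txt", package = "tweettrends"),
            encoding = "UTF-8")
}

#' Tokenize short social-media texts
#'
#' Lowercases; removes URLs and `@`-mentions; keeps hashtags as their
#' bare word; strips punctuation; drops tokens shorter than `min_len`
#' and stopwords.
#'
#' @param text Character vector.
#' @param stopwords Character vector; [default_stopwords()] by default.
#' @param min_len Minimum token length kept (default 2).
#' @return A list of character vectors, one per input element (empty
#'   vectors allowed).
#' @export
tokenize <- function(text, stopwords = default_stopwords(), min_len = 2L) {
  x <- tolower(text)
  x <- gsub("https?://\\S+|www\\.\\S+", " ", x)
  x <- gsub("@[a-z0-9_]+", " ", x)
  x <- gsub("#", " ", x, fixed = TRUE)          # hashtag -> bare word
  x <- gsub("[^a-z0-9']+", " ", x)              # punctuation -> space
  x <- gsub("(^|\\s)'+|'+(\\s|$)", " ", x)      # surrounding apostrophes
  toks <- strsplit(trimws(x), "\\s+")
  lapply(toks, function(tk) {
    tk <- tk[nzchar(tk) & nchar(tk) >= min_len]
    tk[!tk %in% stopwords]
  })
}

#' Build a vocabulary with document-frequency filtering
#'
#' Retains words i whose document frequency `N^(i)` satisfies
#' `min_df <= N^(i) <= max_df_frac * N`; word order is lexicographic,
#' so the result is deterministic.
#'
#' @param docs List of token vectors (one per document).
#' @param min_df Minimum document frequency (default 1).
#' @param max_df_frac Maximum document frequency as a fraction of the
#'   corpus size (default 1).
#' @return Object of class `vocabulary`: list with `words`, `doc_freq`
#'   (named counts `N^(i)`) and `n_docs` (`N`).
#' @export
build_vocabulary <- function(docs, min_df = 1L, max_df_frac = 1) {
  stopifnot(min_df >= 1, max_df_frac > 0, max_df_frac <= 1)
  if (!length(docs)) stop("empty document list")
  n_docs <- length(docs)
  df_tab <- table(unlist(lapply(docs, unique), use.names = FALSE))
  if (!length(df_tab)) stop("no tokens in any document")
  words <- names(df_tab)
  dfreq <- as.integer(df_tab)
  keep <- dfreq >= min_df & dfreq <= max_df_frac * n_docs
  if (!any(keep)) stop("vocabulary is empty after document-frequency filtering")
  ord <- order(words[keep], method = "radix")
  structure(list(words = words[keep][ord],
                 doc_freq = stats::setNames(dfreq[keep][ord], words[keep][ord]),
                 n_docs = n_docs),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d words over %d documents\n",
              length(x$words), x$n_docs))
  invisible(x)
}

#' Write / read a vocabulary as TSV (word, doc_freq)
#' @param vocab A [build_vocabulary()] result.
#' @param path TSV file.
#' @param n_docs Corpus size `N` (stored as a header comment and
#'   re-read by `read_vocabulary`).
#' @return `path` / a `vocabulary`.
#' @export
write_vocabulary <- function(vocab, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# n_docs=%d", vocab$n_docs), con)
  writeLines("word\tdoc_freq", con)
  writeLines(sprintf("%s\t%d", vocab$words, vocab$doc_freq), con)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  n_docs <- as.integer(sub("# n_docs=", "", lines[1], fixed = TRUE))
  df <- utils::read.delim(text = lines[-1], stringsAsFactors = FALSE)
  structure(list(words = df$word,
                 doc_freq = stats::setNames(as.integer(df$doc_freq), df$word),
                 n_docs = n_docs),
            class = "vocabulary")
}

#' tf-idf document encoding
#'
#' Encodes tokenized documents as a sparse nonnegative matrix `V` with
#' `F` rows (words) and `N` columns (documents), with
#' `v_ij = n_ij * ln(N / N^(i))` where `n_ij` is the count of word `i`
#' in document `j` and `N^(i)` its document frequency (scheme
#' `"classic"`). Scheme `"smooth"` uses
#' `n_ij * (ln((1+N)/(1+N^(i))) + 1)`. Words absent from the
#' vocabulary are ignored.
#'
#' @param docs List of token vectors.
#' @param vocab A [build_vocabulary()] result with statistics
#'   compatible with `docs`.
#' @param scheme `"classic"` (unsmoothed, default) or `"smooth"`.
#' @param l2_normalize Scale each document column to unit Euclidean
#'   norm? Default `FALSE`.
#' @param doc_ids Optional document ids (column names); defaults to
#'   `doc1..docN`.
#' @return Object of class `tfidf_matrix`: list with `values` (a
#'   `dgCMatrix`), `vocab` and `doc_ids`.
#' @export
tfidf_matrix <- function(docs, vocab, scheme = c("classic", "smooth"),
                         l2_normalize = FALSE, doc_ids = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(vocab, "vocabulary"))
  if (any(vocab$doc_freq < 1)) stop("inconsistent vocabulary: zero document frequency")
  n <- length(docs)
  if (is.null(doc_ids)) doc_ids <- paste0("doc", seq_len(n))
  stopifnot(length(doc_ids) == n)
  nw <- length(vocab$words)

  ii <- integer(0); jj <- integer(0); cc <- numeric(0)
  idx_of <- stats::setNames(seq_len(nw), vocab$words)
  for (j in seq_len(n)) {
    tk <- docs[[j]]
    tk <- tk[tk %in% vocab$words]
    if (!length(tk)) next
    tab <- table(tk)
    ii <- c(ii, idx_of[names(tab)])
    jj <- c(jj, rep.int(j, length(tab)))
    cc <- c(cc, as.numeric(tab))
  }
  idf <- switch(scheme,
    classic = log(vocab$n_docs / as.numeric(vocab$doc_freq)),
    smooth  = log((1 + vocab$n_docs) / (1 + as.numeric(vocab$doc_freq))) + 1
  )
  V <- Matrix::sparseMatrix(i = ii, j = jj, x = cc * idf[ii],
                            dims = c(nw, n),
                            dimnames = list(vocab$words, doc_ids))
  V <- Matrix::drop0(V)
  if (l2_normalize) {
    nrm <- sqrt(Matrix::colSums(V^2))
    nrm[nrm == 0] <- 1
    V <- V %*% Matrix::Diagonal(x = 1 / nrm)
    dimnames(V) <- list(vocab$words, doc_ids)
  }
  structure(list(values = methods::as(V, "CsparseMatrix"),
                 vocab = vocab, doc_ids = doc_ids),
            class = "tfidf_matrix")
}

#' @export
print.tfidf_matrix <- function(x, ...) {
  cat(sprintf("<tfidf_matrix> %d words x %d documents, %d nonzeros\n",
              nrow(x$values), ncol(x$values), Matrix::nnzero(x$values)))
  invisible(x)
}

#' @export
dim.tfidf_matrix <- function(x) dim(x$values)

#' Write / read a tf-idf matrix in Matrix Market format
#'
#' The sparse matrix goes to `<path>` in MTX coordinate format; the
#' document ids go to a `<path>.docids` sidecar, one per line.
#'
#' @param x A [tfidf_matrix()].
#' @param path MTX file path.
#' @param vocab A [build_vocabulary()] result (row names for the
#'   re-read matrix).
#' @return `path` / a `tfidf_matrix`.
#' @export
write_tfidf <- function(x, path) {
  Matrix::writeMM(x$values, path)
  writeLines(x$doc_ids, paste0(path, ".docids"))
  invisible(path)
}

#' @rdname write_tfidf
#' @export
read_tfidf <- function(path, vocab) {
  V <- methods::as(Matrix::readMM(path), "CsparseMatrix")
  doc_ids <- readLines(paste0(path, ".docids"))
  dimnames(V) <- list(vocab$words, doc_ids)
  structure(list(values = V, vocab = vocab, doc_ids = doc_ids),
            class = "tfidf_matrix")
}
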