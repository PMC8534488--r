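#' Online nonnegative matrix factorization for topic detection
#'
#' Fits the factorization `V ~ W %*% H` with `W, H >= 0` by streaming
#' the document columns of `V` through sequential mini-batches. For
#' each batch q the loadings `H^q` are solved with the previous
#' dictionary `W^(q-1)` held fixed, then the dictionary `W^q` is
#' refreshed with `H^q` held fixed; both steps use multiplicative
#' updates. After every batch the columns of `W` are rescaled to unit
#' Euclidean norm (with compensating row scaling of `H`), which removes
#' the scale ambiguity of the factorization so that argmax topic
#' assignment and top-word rankings are well defined.
#'
#' The word-topic dictionary `W` is `F x k` (words by topics); loadings
#' for any corpus are obtained with [predict.onmf()], which solves a
#' nonnegative least-squares problem per document against the final
#' dictionary.
#'
#' @param V A [tfidf_matrix()], or any nonnegative matrix with words in
#'   rows and documents in columns.
#' @param k Number of topics (`k <= F` required).
#' @param batch_size Documents per mini-batch `s`; batches are
#'   `ceiling(N / s)` contiguous column blocks in input order.
#' @param inner_iters Maximum multiplicative-update iterations for each
#'   of the per-batch H-step and W-step.
#' @param passes Passes over the corpus (default 1; online fitting
#'   normally sees each document once).
#' @param tol Relative-change early-stopping tolerance for the inner
#'   updates.
#' @param seed RNG seed for the uniform(0,1) dictionary
#'   initialization; fits are deterministic given `seed` and input
#'   order.
#' @return An object of class `onmf` with components `W` (the `F x k`
#'   dictionary, unit-norm columns, row names = words), `k`,
#'   `batch_size`, `n_batches`, `objective` (per-batch traces of the
#'   Frobenius objective across inner iterations) and the call.
#' @seealso [predict.onmf()], [assign_topics()], [topic_ratios()],
#'   [top_words()]
#' @export
onmf <- function(V, k, batch_size = 2000L, inner_iters = 100L, passes = 1L,
                 tol = 1e-4, seed = 1L) {
  cl <- match.call()
  X <- if (inherits(V, "tfidf_matrix")) V$values else V
  stopifnot(k >= 1, batch_size >= 1, inner_iters >= 1, passes >= 1, tol > 0)
  if (min(X) < 0) stop("V must be nonnegative")
  f <- nrow(X); n <- ncol(X)
  if (n < 1) stop("V has no documents")
  if (k > f) stop("k exceeds the vocabulary size F")
  if (sum(X) == 0) stop("V is identically zero")
  eps <- .Machine$double.eps

  set.seed(seed)
  W <- matrix(stats::runif(f * k), f, k)
  starts <- seq(1L, n, by = batch_size)
  n_batches <- length(starts)
  objective <- vector("list", n_batches * passes)
  b <- 0L
  for (pass in seq_len(passes)) {
    for (q in seq_len(n_batches)) {
      cols <- starts[q]:min(starts[q] + batch_size - 1L, n)
      Vb <- as.matrix(X[, cols, drop = FALSE])
      s <- length(cols)
      H <- matrix(stats::runif(k * s), k, s)
      b <- b + 1L
      trace <- numeric(0)
      # H-step: W fixed
      WtW <- crossprod(W)
      WtV <- crossprod(W, Vb)
      prev <- Inf
      for (it in seq_len(inner_iters)) {
        H <- H * WtV / (WtW %*% H + eps)
        obj <- sqrt(sum((Vb - W %*% H)^2))
        trace <- c(trace, obj)
        if (is.finite(prev) && abs(prev - obj) <= tol * max(prev, eps)) break
        prev <- obj
      }
      # W-step: H fixed
      HHt <- tcrossprod(H)
      VHt <- tcrossprod(Vb, H)
      prev <- Inf
      for (it in seq_len(inner_iters)) {
        W <- W * VHt / (W %*% HHt + eps)
        obj <- sqrt(sum((Vb - W %*% H)^2))
        trace <- c(trace, obj)
        if (is.finite(prev) && abs(prev - obj) <= tol * max(prev, eps)) break
        prev <- obj
      }
      objective[[b]] <- trace
      # unit-norm columns; compensating H scaling keeps W %*% H fixed
      nrm <- sqrt(colSums(W^2))
      nrm[nrm < eps] <- 1
      W <- sweep(W, 2, nrm, "/")
    }
  }
  rownames(W) <- rownames(X)
  structure(list(W = W, k = k, batch_size = as.integer(batch_size),
                 inner_iters = as.integer(inner_iters),
                 passes = as.integer(passes), tol = tol, seed = seed,
                 n_batches = n_batches, objective = objective[seq_len(b)],
                 call = cl),
            class = "onmf")
}

#' @export
print.onmf <- function(x, ...) {
  cat("Online NMF topic model\n")
  cat("Call: "); print(x$call)
  cat(sprintf("%d topics over %d words; %d batch(es) of size <= %d, %d pass(es)\n",
              x$k, nrow(x$W), x$n_batches, x$batch_size, x$passes))
  invisible(x)
}

#' @export
summary.onmf <- function(object, n_words = 5L, ...) {
  tops <- lapply(seq_len(object$k), function(t) top_words(object, t, n_words))
  final_obj <- vapply(object$objective, function(tr) tr[length(tr)], 0)
  structure(list(k = object$k, f = nrow(object$W),
                 n_batches = object$n_batches,
                 final_objective = final_obj, top = tops),
            class = "summary.onmf")
}

#' @export
print.summary.onmf <- function(x, ...) {
  cat(sprintf("Online NMF: %d topics, %d words, %d batch update(s)\n",
              x$k, x$f, x$n_batches))
  cat(sprintf("final per-batch objective: %s\n",
              paste(signif(x$final_objective, 4), collapse = ", ")))
  for (t in seq_len(x$k)) {
    cat(sprintf("topic %d: %s\n", t, paste(x$top[[t]]$word, collapse = " ")))
  }
  invisible(x)
}

#' @describeIn onmf The fitted word-topic dictionary `W`.
#' @param object,... An `onmf` fit; further arguments ignored.
#' @export
coef.onmf <- function(object, ...) object$W

#' @export
plot.onmf <- function(x, ...) {
  obj <- unlist(x$objective)
  graphics::plot(obj, type = "l", xlab = "inner iteration (all batches)",
                 ylab = "Frobenius objective",
                 main = "ONMF per-batch objective trace", ...)
  invisible(x)
}

#' Infer topic loadings for documents
#'
#' Solves, for each document column `v_j`, the nonnegative
#' least-squares problem `min_{h >= 0} || v_j - W h ||` against the
#' fitted dictionary. Zero documents get zero loadings.
#'
#' @param object An [onmf()] fit.
#' @param newdata A [tfidf_matrix()] or matrix with the same rows
#'   (words) as the dictionary.
#' @param ... Ignored.
#' @return Object of class `topic_loadings`: list with `H` (`k x N`
#'   nonnegative) and `doc_ids`.
#' @export
predict.onmf <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "tfidf_matrix")) newdata$values else newdata
  if (nrow(X) != nrow(object$W)) {
    stop(sprintf("dimension mismatch: dictionary has %d words, data has %d rows",
                 nrow(object$W), nrow(X)))
  }
  doc_ids <- colnames(X)
  if (is.null(doc_ids)) doc_ids <- paste0("doc", seq_len(ncol(X)))
  W <- object$W
  H <- matrix(0, object$k, ncol(X), dimnames = list(NULL, doc_ids))
  for (j in seq_len(ncol(X))) {
    v <- as.numeric(X[, j])
    if (any(v != 0)) H[, j] <- pracma::lsqnonneg(W, v)$x
  }
  structure(list(H = H, doc_ids = doc_ids), class = "topic_loadings")
}

#' @export
print.topic_loadings <- function(x, ...) {
  cat(sprintf("<topic_loadings> %d topics x %d documents\n", nrow(x$H), ncol(x$H)))
  invisible(x)
}

#' Representative topic per document
#'
#' The representative topic of a document is the argmax of its loading
#' column; ties are broken by the smallest topic index, and all-zero
#' columns are left unassigned (`NA`).
#'
#' @param loadings A [predict.onmf()] result (or bare `k x N` matrix).
#' @return Object of class `topic_assignment`: list with `topic`
#'   (integer vector, `NA` = unassigned), `doc_ids` and `k`.
#' @export
assign_topics <- function(loadings) {
  H <- if (inherits(loadings, "topic_loadings")) loadings$H else loadings
  doc_ids <- colnames(H)
  if (is.null(doc_ids)) doc_ids <- paste0("doc", seq_len(ncol(H)))
  topic <- integer(ncol(H))
  for (j in seq_len(ncol(H))) {
    h <- H[, j]
    topic[j] <- if (all(h == 0)) NA_integer_ else which.max(h)
  }
  structure(list(topic = topic, doc_ids = doc_ids, k = nrow(H)),
            class = "topic_assignment")
}

#' @export
print.topic_assignment <- function(x, ...) {
  cat(sprintf("<topic_assignment> %d documents, %d unassigned, k = %d\n",
              length(x$topic), sum(is.na(x$topic)), x$k))
  invisible(x)
}

#' Topic ratios
#'
#' Fraction of assigned documents whose representative topic is `t`,
#' for every topic `t = 1..k`; unassigned documents are excluded from
#' the denominator. The ratios sum to 1.
#'
#' @param assign A [assign_topics()] result.
#' @param k Number of topics; defaults to `assign$k`.
#' @return Numeric length-`k` vector of ratios.
#' @export
topic_ratios <- function(assign, k = assign$k) {
  topic <- if (inherits(assign, "topic_assignment")) assign$topic else assign
  topic <- topic[!is.na(topic)]
  if (!length(topic)) stop("no assigned documents")
  as.numeric(tabulate(topic, nbins = k)) / length(topic)
}

#' Retain topics at or above the average ratio
#'
#' Discards "insignificant" topics whose ratio falls strictly below the
#' average ratio `1/k`; with `k = 50` the cutoff is 2%. Topics exactly
#' at the average are kept.
#'
#' @param ratios A [topic_ratios()] vector.
#' @param k Number of topics (default `length(ratios)`).
#' @return Integer vector of retained topic indices.
#' @export
filter_topics <- function(ratios, k = length(ratios)) {
  which(ratios >= 1 / k)
}

#' Top-weighted words of a topic
#'
#' @param model An [onmf()] fit with word row names.
#' @param topic Topic index in `1..k`.
#' @param n Number of words (clamped to the vocabulary size).
#' @return data.frame with columns `word` and `weight`, in descending
#'   weight order, ties broken lexicographically.
#' @export
top_words <- function(model, topic, n = 10L) {
  stopifnot(inherits(model, "onmf"), topic >= 1, topic <= model$k)
  w <- model$W[, topic]
  words <- rownames(model$W)
  if (is.null(words)) words <- paste0("w", seq_along(w))
  n <- max(0L, min(as.integer(n), length(w)))
  ord <- order(-w, words, method = "radix")[seq_len(n)]
  data.frame(word = words[ord], weight = unname(w[ord]),
             stringsAsFactors = FALSE)
}
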