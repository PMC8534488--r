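test_that("degenerate inputs are rejected", {
  expect_error(onmf(matrix(0, 4, 5), k = 2), "zero")
  expect_error(onmf(matrix(1, 4, 5), k = 6), "exceeds")
  expect_error(onmf(matrix(-1, 4, 5), k = 2), "nonnegative")
})

test_that("a corpus with exact low-rank structure is reconstructed closely", {
  set.seed(5)
  Wt <- matrix(stats::rgamma(20 * 2, 1), 20, 2)
  Ht <- matrix(stats::rgamma(2 * 200, 1), 2, 200)
  V <- Wt %*% Ht
  fit <- onmf(V, k = 2, batch_size = 50, inner_iters = 300, passes = 2, seed = 3)
  H <- predict(fit, V)
  rel_err <- sqrt(sum((V - fit$W %*% H$H)^2)) / sqrt(sum(V^2))
  expect_lte(rel_err, 0.05)
  expect_gte(min(fit$W), 0)
  expect_gte(min(H$H), 0)
  # unit-norm dictionary columns
  expect_equal(unname(sqrt(colSums(fit$W^2))), rep(1, 2), tolerance = 1e-8)
})

test_that("single-batch fit matches the batch multiplicative-update oracle within 1%", {
  set.seed(99)
  V <- matrix(stats::rgamma(50 * 500, 0.5), 50, 500)
  fit <- onmf(V, k = 6, batch_size = 500, inner_iters = 300, passes = 8,
              tol = 1e-6, seed = 11)
  H <- predict(fit, V)
  obj <- sqrt(sum((V - fit$W %*% H$H)^2))
  ref <- batch_nmf_oracle(V, k = 6, iters = 2400, seed = 11)
  expect_lte(abs(obj - ref$objective) / ref$objective, 0.01)
})

test_that("rank-1 fit matches the alternating rank-1 solution", {
  set.seed(5)
  V <- matrix(stats::rgamma(20 * 2, 1), 20, 2) %*% matrix(stats::rgamma(2 * 200, 1), 2, 200)
  fit <- onmf(V, k = 1, batch_size = 1000, inner_iters = 300, passes = 2, seed = 3)
  H <- predict(fit, V)
  err <- sqrt(sum((V - fit$W %*% H$H)^2))
  # best rank-1 of a nonnegative matrix is its truncated SVD (Perron-Frobenius)
  s <- svd(V)
  expect_lte(err, 1.001 * sqrt(sum(s$d[-1]^2)))
})

test_that("per-batch objective traces are non-increasing", {
  set.seed(1)
  V <- matrix(stats::rgamma(30 * 120, 0.7), 30, 120)
  fit <- onmf(V, k = 4, batch_size = 40, inner_iters = 50, seed = 2)
  expect_equal(fit$n_batches, 3)
  for (trace in fit$objective) {
    expect_true(all(diff(trace) <= 1e-8 * trace[1]))
  }
})

test_that("loading inference solves nonnegative least squares per column", {
  set.seed(10)
  W <- matrix(stats::runif(10 * 3), 10, 3)
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  fit <- structure(list(W = W, k = 3), class = "onmf")
  # exact representation: a dictionary column maps to a scaled unit vector
  H1 <- predict(fit, cbind(2.5 * W[, 2]))
  expect_equal(as.numeric(H1$H), c(0, 2.5, 0), tolerance = 1e-8)
  # zero document -> zero loadings
  H0 <- predict(fit, cbind(rep(0, 10)))
  expect_equal(as.numeric(H0$H), c(0, 0, 0))
  # full-column-rank recovery of a known nonnegative solution
  h <- c(0.3, 0, 1.7)
  Hr <- predict(fit, cbind(W %*% h))
  expect_equal(as.numeric(Hr$H), h, tolerance = 1e-6)
  expect_error(predict(fit, matrix(1, 4, 2)), "mismatch")
})

test_that("argmax assignment breaks ties low and leaves zero columns unassigned", {
  H <- cbind(c(0.1, 0.9), c(0.5, 0.5), c(0, 0))
  a <- assign_topics(H)
  expect_equal(a$topic, c(2L, 1L, NA))
  expect_equal(sum(is.na(a$topic)), 1)
})

test_that("assignment is invariant to positive rescaling of document columns", {
  fx <- easy_fixture()
  fit <- onmf(fx$V, k = 8, batch_size = 500, seed = 101)
  cols <- 1:40
  V1 <- as.matrix(fx$V$values[, cols])
  scales <- stats::runif(length(cols), 0.2, 5)
  V2 <- sweep(V1, 2, scales, "*")
  a1 <- assign_topics(predict(fit, V1))
  a2 <- assign_topics(predict(fit, V2))
  expect_equal(a1$topic, a2$topic)
  .fixtures$easy_fit <- fit  # reused by later tests
})

test_that("topic ratios sum to one over assigned documents and drop the unassigned", {
  a <- structure(list(topic = c(1L, 1L, 2L, 3L, NA), doc_ids = letters[1:5], k = 3L),
                 class = "topic_assignment")
  r <- topic_ratios(a)
  expect_equal(r, c(0.5, 0.25, 0.25))
  expect_equal(sum(r), 1)
  one <- structure(list(topic = rep(2L, 4), doc_ids = letters[1:4], k = 3L),
                   class = "topic_assignment")
  expect_equal(topic_ratios(one), c(0, 1, 0))
  none <- structure(list(topic = c(NA_integer_, NA_integer_), doc_ids = c("a", "b"),
                         k = 2L), class = "topic_assignment")
  expect_error(topic_ratios(none), "no assigned")
})

test_that("the ratio filter keeps topics at or above the 1/k average", {
  r <- c(0.5, 0.3, 0.2, rep(0, 47))
  expect_equal(filter_topics(r, 50), c(1, 2, 3))
  # uniform assignment over k = 50 puts every topic exactly at the 2% average
  expect_equal(filter_topics(rep(0.02, 50), 50), 1:50)
})

test_that("top words rank by weight with lexicographic tie-breaks", {
  W <- cbind(c(0, 0.9, 0), c(0.4, 0.4, 0.1))
  rownames(W) <- c("beta", "alpha", "gamma")
  fit <- structure(list(W = W, k = 2), class = "onmf")
  expect_equal(top_words(fit, 1, 1)$word, "alpha")
  expect_equal(top_words(fit, 2, 2)$word, c("alpha", "beta"))  # tie -> lexicographic
  expect_equal(nrow(top_words(fit, 1, 0)), 0)
  expect_equal(nrow(top_words(fit, 1, 99)), 3)  # clamped to F
})

test_that("planted anchor words dominate the matched topics' top words", {
  fx <- easy_fixture()
  fit <- .fixtures$easy_fit
  m <- match_topics(fx$gen$truth$topic_word, coef(fit))
  expect_gte(m$mean_cosine, 0.80)
  anchors_per_topic <- fx$gen$truth$config$anchors_per_topic
  for (i in seq_len(nrow(m$pairs))) {
    truth_row <- fx$gen$truth$topic_word[m$pairs$truth[i], ]
    anchors <- names(sort(truth_row, decreasing = TRUE))[seq_len(anchors_per_topic)]
    tw <- top_words(fit, m$pairs$learned[i], anchors_per_topic)
    expect_gte(length(intersect(tw$word, anchors)), anchors_per_topic - 3)
  }
})
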