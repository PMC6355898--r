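test_that("rank-1 corpus yields collinear word vectors", {
  corp <- corpus(list(c("sun", "rain", "wind", "sun"),
                      c("sun", "rain", "wind", "sun")))
  sp <- build_space(corp, k = 1, weighting = "raw")
  toks <- names(sp$vocabulary)
  for (a in toks) for (b in toks) {
    expect_equal(cosine_similarity(word_vector(sp, a), word_vector(sp, b)),
                 1, tolerance = 1e-12)
  }
  # identical documents carry zero entropy signal: log-entropy weighting
  # drops every term, which must be reported, not silently tolerated
  expect_error(build_space(corp, k = 1, weighting = "log-entropy"),
               "zero weight")
})

test_that("two disjoint topic blocks separate: within > between cosine, vs brute-force SVD oracle", {
  docs <- list(c("apple", "pear", "plum", "apple"),
               c("pear", "plum", "apple", "pear"),
               c("iron", "steel", "zinc", "iron"),
               c("steel", "zinc", "iron", "zinc"))
  corp <- corpus(docs)
  sp <- build_space(corp, k = 2)

  # independent oracle: rebuild the weighted matrix and SVD it directly
  vocab <- sort(unique(unlist(docs)))
  tdm <- sapply(docs, function(d) {
    v <- table(factor(d, levels = vocab)); as.numeric(v)
  })
  gf <- rowSums(tdm)
  p <- tdm / gf
  g <- 1 + rowSums(ifelse(p > 0, p * log2(p), 0)) / log2(ncol(tdm))
  w <- log2(1 + tdm) * g
  sv <- svd(w)
  oracle_vec <- sv$u[, 1:2] %*% diag(sv$d[1:2])
  rownames(oracle_vec) <- vocab
  cos <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  fruit <- c("apple", "pear", "plum"); metal <- c("iron", "steel", "zinc")
  pair_means <- function(vecs) {
    within <- c(cos(vecs["apple", ], vecs["pear", ]),
                cos(vecs["iron", ], vecs["steel", ]))
    between <- c(cos(vecs["apple", ], vecs["iron", ]),
                 cos(vecs["pear", ], vecs["zinc", ]))
    c(mean(within), mean(between))
  }
  expect_gt(pair_means(oracle_vec)[1], pair_means(oracle_vec)[2])
  for (a in c(fruit, metal)) for (b in c(fruit, metal)) {
    expect_equal(cosine_similarity(word_vector(sp, a), word_vector(sp, b)),
                 cos(oracle_vec[a, ], oracle_vec[b, ]), tolerance = 1e-8)
  }
})

test_that("full-rank factorization reproduces the weighted Gram matrix", {
  tts <- two_topic_space(seed = 3, k = 4, words_per_topic = 8, n_docs = 6)
  corp <- tts$corpus
  vocab0 <- sort(unique(unlist(corp$documents)))
  tdm <- sapply(corp$documents, function(d)
    as.numeric(table(factor(d, levels = vocab0))))
  gf <- rowSums(tdm)
  p <- tdm / gf
  g <- 1 + rowSums(ifelse(p > 0, p * log2(p), 0)) / log2(ncol(tdm))
  keep <- g > 1e-12
  w <- (log2(1 + tdm) * g)[keep, , drop = FALSE]
  r <- qr(w)$rank
  sp <- build_space(corp, k = r)
  # vectors = U_k S_k, so at full rank vectors %*% t(vectors) = W W'
  gram_fit <- tcrossprod(sp$vectors[vocab0[keep], , drop = FALSE])
  gram_true <- tcrossprod(w)
  expect_lt(norm(gram_fit - gram_true, "F"), 1e-8 * norm(gram_true, "F"))
})

test_that("build_space validates k and frequency filtering", {
  corp <- corpus(list(c("x", "y"), c("y", "z"), c("x", "z")))
  expect_error(build_space(corp, k = 50), "rank bound")
  expect_error(build_space(corp, k = 0), "positive integer")
  expect_error(build_space(corp, k = 1, min_doc_freq = 10),
               "empty vocabulary")
})

test_that("word lookup normalizes case and marks OOV distinctly", {
  sp <- toy_space()
  expect_equal(word_vector(sp, "a"), c(1, 0, 0))
  expect_equal(word_vector(sp, "A"), c(1, 0, 0))
  expect_equal(word_vector(sp, "b,"), c(0, 1, 0))
  expect_null(word_vector(sp, "unseen"))
})

test_that("passage vectors are bag-of-words means with OOV accounting", {
  sp <- toy_space()
  one <- passage_vector(sp, "b")
  expect_equal(one$values, c(0, 1, 0))
  expect_equal(one$n_contributing, 1L)

  # 3 known + 2 OOV -> mean of the 3 known vectors (hand-computed)
  pv <- passage_vector(sp, c("a", "qq", "b", "zz", "c"))
  expect_equal(pv$values, c(1, 1, 1) / 3)
  expect_equal(pv$n_contributing, 3L)

  # order invariance, including under duplication-preserving shuffles
  toks <- c("a", "b", "b", "d", "c", "a")
  set.seed(1)
  for (i in 1:5) {
    perm <- sample(toks)
    expect_identical(passage_vector(sp, perm)$values,
                     passage_vector(sp, toks)$values)
  }

  all_oov <- passage_vector(sp, c("qq", "zz"))
  expect_false(all_oov$defined)
  expect_equal(all_oov$n_contributing, 0L)
  expect_error(cosine_similarity(all_oov, c(1, 0, 0)), "undefined")
})

test_that("cosine similarity: identities, closed form, scale invariance", {
  expect_equal(cosine_similarity(c(2, 1), c(2, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 0.7071, tolerance = 1e-4)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
  set.seed(42)
  for (i in 1:20) {
    u <- rnorm(5); v <- rnorm(5)
    a <- runif(1, 0.01, 100); b <- runif(1, 0.01, 100)
    expect_equal(cosine_similarity(a * u, b * v), cosine_similarity(u, v),
                 tolerance = 1e-12)
    expect_equal(cosine_similarity(u, v), cosine_similarity(v, u))
  }
})

test_that("space serialization round-trips bit-exactly", {
  tts <- two_topic_space(seed = 7, k = 3)
  sp <- tts$space
  prefix <- file.path(withr::local_tempdir(), "space")
  write_space(sp, prefix)
  back <- read_space(prefix)
  expect_identical(back$vectors, sp$vectors)
  expect_identical(back$vocabulary, sp$vocabulary)
  expect_identical(unname(back$global_weights), unname(sp$global_weights))
  expect_identical(back$singular_values, sp$singular_values)
  expect_identical(back$k, sp$k)
})

test_that("space construction is deterministic with a fixed sign convention", {
  a <- two_topic_space(seed = 5, k = 3)$space
  b <- two_topic_space(seed = 5, k = 3)$space
  expect_identical(a$vectors, b$vectors)
  for (c in seq_len(a$k)) {
    expect_gt(a$vectors[which.max(abs(a$vectors[, c])), c], 0)
  }
})
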