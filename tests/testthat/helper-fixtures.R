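# Hand-built semantic space with known geometry: vectors supplied directly,
# bypassing SVD, so expected cosines can be computed on paper.
manual_space <- function(tokens, vectors) {
  vectors <- as.matrix(vectors)
  rownames(vectors) <- tokens
  vocab <- seq_along(tokens)
  names(vocab) <- tokens
  structure(list(vocabulary = vocab, vectors = vectors,
                 k = ncol(vectors),
                 global_weights = stats::setNames(rep(1, length(tokens)),
                                                  tokens),
                 singular_values = rep(1, ncol(vectors)),
                 weighting = "raw"),
            class = "semantic_space")
}
toy_space <- function() {
  manual_space(
    c("a", "b", "c", "d", "e"),
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(2, 0, 0)))
}

# two-topic space trained from a generated corpus (disjoint vocabularies ->
# exactly orthogonal topic subspaces)
two_topic_space <- function(seed = 1, k = 4, words_per_topic = 30,
                            n_docs = 24) {
  spec <- topic_model_spec(n_topics = 2, words_per_topic = words_per_topic)
  corp <- generate_corpus(spec, n_docs = n_docs, seed = seed)
  list(spec = spec, corpus = corp, space = build_space(corp, k = k))
}

# independent brute-force coherence oracle: recompute every window from
# scratch with passage_vector + cosine_similarity (no rolling sums)
brute_global <- function(resp, proto, space, window) {
  n <- length(resp$tokens)
  out <- rep(NA_real_, n)
  if (n < window) return(out)
  for (i in window:n) {
    pv <- passage_vector(space, resp$tokens[(i - window + 1):i])
    if (!pv$defined) next
    out[i] <- 100 * max(0, cosine_similarity(pv, proto$values))
  }
  out
}
brute_local <- function(resp, space, window) {
  n <- length(resp$tokens)
  out <- rep(NA_real_, n)
  if (n < 2 * window) return(out)
  for (i in (2 * window):n) {
    cur <- passage_vector(space, resp$tokens[(i - window + 1):i])
    prev <- passage_vector(space, resp$tokens[(i - 2 * window + 1):(i - window)])
    if (!cur$defined || !prev$defined) next
    out[i] <- 100 * max(0, cosine_similarity(cur, prev))
  }
  out
}

# independent connected-component labeller (union-find over voxel pairs),
# used as the oracle for label_clusters / the cluster simulation
oracle_max_cluster <- function(supra, connectivity = 26) {
  d <- dim(supra)
  idx <- which(supra)
  if (length(idx) == 0) return(0L)
  coords <- arrayInd(idx, d)
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (b <= a) next
      dd <- abs(coords[a, ] - coords[b, ])
      adjacent <- if (connectivity == 26) all(dd <= 1) else
        sum(dd) == 1
      if (adjacent) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_along(idx), find, 1L)
  max(table(roots))
}

toy_norms <- function() {
  norms_table(
    data.frame(word = c("dog", "cat", "table", "run", "the", "a"),
               frequency = c(3.2, 3.0, 2.5, 3.5, 5.0, 5.1),
               concreteness = c(4.8, 4.9, 4.5, 3.0, 1.5, 1.4),
               age_of_acquisition = c(3, 3.5, 4, 4.5, 2.5, 2.4),
               semantic_diversity = c(1.5, 1.4, 1.2, 2.0, 2.4, 2.5),
               phoneme_length = c(3, 3, 5, 3, 2, 1)),
    closed_class = c("the", "a"),
    nouns = c("dog", "cat", "table"))
}
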