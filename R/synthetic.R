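#' Specification of a synthetic topic model
#'
#' Defines the ground-truth topic structure for generated corpora and
#' responses: each topic owns a private vocabulary, an optional pool of
#' shared words is mixed in, and word emission within a pool follows a
#' Zipf-like law whose exponent is the concentration (higher = probability
#' mass more concentrated on the top words).  The emission distributions
#' are deterministic functions of the spec, so corpora and responses
#' generated separately share the same topic vocabulary.
#'
#' @param n_topics number of topics (>= 2; default 6, a desk-scale stand-in
#'   for a task probing many distinct prompt topics).
#' @param words_per_topic private vocabulary size per topic.
#' @param shared_fraction probability that a token is drawn from the shared
#'   pool (in `[0, 1]`).
#' @param n_shared size of the shared pool.
#' @param concentration Zipf exponent of the emission law (default 1).
#' @return object of class `topic_model_spec`.
#' @export
topic_model_spec <- function(n_topics = 6L, words_per_topic = 40L,
                             shared_fraction = 0, n_shared = 20L,
                             concentration = 1) {
  if (n_topics < 2L) stop("need at least 2 topics")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must be in [0, 1]")
  structure(list(n_topics = as.integer(n_topics),
                 words_per_topic = as.integer(words_per_topic),
                 shared_fraction = shared_fraction,
                 n_shared = as.integer(n_shared),
                 concentration = concentration),
            class = "topic_model_spec")
}

topic_words <- function(spec, topic) {
  sprintf("topic%dword%03d", topic, seq_len(spec$words_per_topic))
}
shared_words <- function(spec) {
  if (spec$n_shared == 0L) character(0) else
    sprintf("sharedword%03d", seq_len(spec$n_shared))
}
zipf_probs <- function(n, s) {
  w <- (1 / seq_len(n))^s
  w / sum(w)
}

## draw n tokens from one topic's emission distribution
draw_topic_tokens <- function(spec, topic, n) {
  from_shared <- if (spec$shared_fraction > 0 && spec$n_shared > 0)
    stats::runif(n) < spec$shared_fraction else rep(FALSE, n)
  out <- character(n)
  if (any(!from_shared))
    out[!from_shared] <- sample(topic_words(spec, topic), sum(!from_shared),
                                replace = TRUE,
                                prob = zipf_probs(spec$words_per_topic,
                                                  spec$concentration))
  if (any(from_shared))
    out[from_shared] <- sample(shared_words(spec), sum(from_shared),
                               replace = TRUE,
                               prob = zipf_probs(spec$n_shared,
                                                 spec$concentration))
  out
}

#' Generate a topic-structured training corpus
#'
#' Documents are drawn from the per-topic unigram distributions of the
#' spec, cycling through topics, and the topic labels are retained as
#' ground truth (attribute `"topics"`).  Deterministic given `(spec, seed)`.
#'
#' @param spec a [topic_model_spec()].
#' @param n_docs number of documents.
#' @param seed RNG seed.
#' @param doc_length tokens per document (default 100).
#' @return a [corpus()] with attribute `topics`.
#' @export
generate_corpus <- function(spec, n_docs = 40L, seed = 1L,
                            doc_length = 100L) {
  stopifnot(inherits(spec, "topic_model_spec"))
  set.seed(seed)
  topics <- rep_len(seq_len(spec$n_topics), n_docs)
  docs <- lapply(topics, function(tp) draw_topic_tokens(spec, tp, doc_length))
  out <- corpus(docs, doc_ids = sprintf("doc%03d_t%d", seq_len(n_docs),
                                        topics))
  attr(out, "topics") <- topics
  out
}

#' Specification of coherence drift in generated responses
#'
#' On-topic word proportion starts at `p0` and declines by `delta` per 5-s
#' block, emulating speech that drifts off topic over the production
#' period.  Defaults: 10 words per block (the observed production rate) and
#' 10 blocks (a 50-s period); `p0 = 0.95`, `delta = 0.05` give a response
#' that starts nearly fully on topic and is near chance-level topical focus
#' by the final block.
#'
#' @param p0 initial on-topic proportion, in `[0, 1]`.
#' @param delta per-block decline.
#' @param words_per_block speech rate (words per block, default 10).
#' @param n_blocks blocks per response (default 10).
#' @param block_length seconds per block (default 5).
#' @return object of class `drift_spec`.
#' @export
drift_spec <- function(p0 = 0.95, delta = 0.05, words_per_block = 10L,
                       n_blocks = 10L, block_length = 5) {
  if (p0 < 0 || p0 > 1) stop("p0 must be in [0, 1]")
  if (p0 - (n_blocks - 1) * delta < 0)
    stop("infeasible drift: p0 - (n_blocks - 1) * delta = ",
         p0 - (n_blocks - 1) * delta, " < 0")
  structure(list(p0 = p0, delta = delta,
                 words_per_block = as.integer(words_per_block),
                 n_blocks = as.integer(n_blocks),
                 block_length = block_length),
            class = "drift_spec")
}

#' Generate drifting responses to a prompt
#'
#' Per participant and block, each word is on-topic with probability
#' `p0 - (block - 1) * delta`; off-topic words come in runs (excursions),
#' each excursion drawn from one randomly chosen other topic, so stretches
#' of off-topic speech are locally self-consistent (letting local and
#' global coherence dissociate).  Word onsets are uniform at the
#' words-per-block rate.  The per-block ground-truth on-topic proportion is
#' attached as attribute `"on_topic"` (participants x blocks).
#'
#' @param topic_spec a [topic_model_spec()].
#' @param prompt_topic index of the prompt's topic.
#' @param drift a [drift_spec()].
#' @param n_participants number of responses.
#' @param seed RNG seed.
#' @param prompt_id identifier for the prompt (default
#'   `paste0("prompt", prompt_topic)`).
#' @return list of [response()] objects with attribute `on_topic`.
#' @export
generate_responses <- function(topic_spec, prompt_topic, drift,
                               n_participants = 8L, seed = 1L,
                               prompt_id = NULL) {
  stopifnot(inherits(topic_spec, "topic_model_spec"),
            inherits(drift, "drift_spec"))
  if (prompt_topic < 1L || prompt_topic > topic_spec$n_topics)
    stop("prompt_topic out of range")
  if (is.null(prompt_id)) prompt_id <- paste0("prompt", prompt_topic)
  set.seed(seed)
  period <- drift$n_blocks * drift$block_length
  wpb <- drift$words_per_block
  on_topic <- matrix(NA_real_, n_participants, drift$n_blocks)
  out <- vector("list", n_participants)
  other_topics <- setdiff(seq_len(topic_spec$n_topics), prompt_topic)
  for (p in seq_len(n_participants)) {
    tokens <- character(0)
    for (b in seq_len(drift$n_blocks)) {
      pb <- drift$p0 - (b - 1) * drift$delta
      on <- stats::runif(wpb) < pb
      on_topic[p, b] <- mean(on)
      blk <- character(wpb)
      if (any(on))
        blk[on] <- draw_topic_tokens(topic_spec, prompt_topic, sum(on))
      if (any(!on)) {
        ## consecutive off-topic words form excursions sharing one topic
        runs <- rle(!on)
        pos <- 1L
        for (r in seq_along(runs$lengths)) {
          len <- runs$lengths[r]
          if (runs$values[r]) {
            tp <- if (length(other_topics) == 1L) other_topics else
              sample(other_topics, 1L)
            blk[pos:(pos + len - 1L)] <- draw_topic_tokens(topic_spec, tp,
                                                           len)
          }
          pos <- pos + len
        }
      }
      tokens <- c(tokens, blk)
    }
    onsets <- (seq_along(tokens) - 1) * drift$block_length / wpb
    out[[p]] <- response(sprintf("p%02d", p), prompt_id, tokens,
                         onsets = onsets, period_length = period)
  }
  attr(out, "on_topic") <- on_topic
  out
}

#' Generate a synthetic lexical norms table
#'
#' Random but seed-fixed norms for a vocabulary, with disjoint closed-class
#' and noun lists carved from it.  Ranges loosely follow published norm
#' sets: log-frequency ~ N(3, 1), concreteness in 1-5, age of acquisition
#' in 2-14 years, semantic diversity in 0.5-2.5, phoneme length in 2-12.
#'
#' @param vocabulary character vector of words.
#' @param seed RNG seed.
#' @param closed_class_fraction,noun_fraction fractions of the vocabulary
#'   assigned to each (disjoint) list.
#' @return a [norms_table()].
#' @export
generate_norms <- function(vocabulary, seed = 1L,
                           closed_class_fraction = 0.15,
                           noun_fraction = 0.4) {
  vocabulary <- unique(normalize_tokens(vocabulary))
  n <- length(vocabulary)
  set.seed(seed)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  norms <- data.frame(
    word = vocabulary,
    frequency = stats::rnorm(n, 3, 1),
    concreteness = clamp(stats::rnorm(n, 3, 0.8), 1, 5),
    age_of_acquisition = clamp(stats::rnorm(n, 7, 2.5), 2, 14),
    semantic_diversity = clamp(stats::rnorm(n, 1.5, 0.4), 0.5, 2.5),
    phoneme_length = pmax(2L, stats::rpois(n, 5)))
  shuffled <- sample(vocabulary)
  n_cc <- max(1L, round(closed_class_fraction * n))
  n_noun <- max(1L, round(noun_fraction * n))
  norms_table(norms, closed_class = shuffled[seq_len(n_cc)],
              nouns = shuffled[n_cc + seq_len(min(n_noun, n - n_cc))])
}

#' Generate a block-measure table with planted factor structure
#'
#' Draws factor scores for each block and maps them through a planted
#' loading matrix plus Gaussian noise, producing a measures table whose
#' latent structure is known — the ground truth for factor-recovery tests.
#' The default loading pattern mirrors the four interpreted speech factors
#' (complexity, specificity, coherence, verbosity) over nine measures.
#'
#' @param n_blocks rows to generate.
#' @param loadings measures x factors loading matrix; default
#'   [default_planted_loadings()].
#' @param noise_sd unique-variance SD (default 0.3).
#' @param seed RNG seed.
#' @return list with `table` (data.frame), `loadings`, `scores`.
#' @export
generate_measure_table <- function(n_blocks = 200L, loadings = NULL,
                                   noise_sd = 0.3, seed = 1L) {
  if (is.null(loadings)) loadings <- default_planted_loadings()
  loadings <- as.matrix(loadings)
  set.seed(seed)
  nf <- ncol(loadings)
  scores <- matrix(stats::rnorm(n_blocks * nf), n_blocks, nf)
  x <- scores %*% t(loadings) +
    matrix(stats::rnorm(n_blocks * nrow(loadings), sd = noise_sd),
           n_blocks, nrow(loadings))
  colnames(x) <- rownames(loadings)
  list(table = as.data.frame(x), loadings = loadings, scores = scores)
}

#' Default planted loading pattern for four speech factors
#'
#' Nine measures loading on four latent factors: lexical complexity
#' (frequency (-), age of acquisition, phoneme length), specificity
#' (concreteness, semantic diversity (-)), coherence (global and local
#' coherence), and verbosity (word count, type:token ratio (-)).
#'
#' @return 9 x 4 numeric matrix.
#' @export
default_planted_loadings <- function() {
  m <- matrix(0, 9, 4, dimnames = list(
    c("noun_frequency", "noun_aoa", "noun_phoneme_length",
      "noun_concreteness", "noun_semantic_diversity",
      "global_coherence", "local_coherence",
      "n_words", "type_token_ratio"),
    c("complexity", "specificity", "coherence", "verbosity")))
  m["noun_frequency", "complexity"] <- -0.8
  m["noun_aoa", "complexity"] <- 0.8
  m["noun_phoneme_length", "complexity"] <- 0.7
  m["noun_concreteness", "specificity"] <- 0.8
  m["noun_semantic_diversity", "specificity"] <- -0.7
  m["global_coherence", "coherence"] <- 0.85
  m["local_coherence", "coherence"] <- 0.7
  m["n_words", "verbosity"] <- 0.8
  m["type_token_ratio", "verbosity"] <- -0.7
  m
}

#' Specification of a synthetic BOLD simulation
#'
#' @param dims 3-D grid dimensions (desk scale; default `c(20, 20, 20)`).
#' @param noise_sd Gaussian noise SD (default 1).
#' @param ar1 lag-1 autocorrelation of the noise (default 0.3).
#' @param tr repetition time (default 2.2 s).
#' @param seed RNG seed.
#' @return object of class `bold_sim_spec`.
#' @export
bold_sim_spec <- function(dims = c(20L, 20L, 20L), noise_sd = 1, ar1 = 0.3,
                          tr = 2.2, seed = 1L) {
  if (length(dims) != 3L || any(dims < 1L)) stop("dims must be 3 positive")
  if (prod(dims) > 20^3 * 8)
    stop("grid too large for a desk-scale simulation")
  structure(list(dims = as.integer(dims), noise_sd = noise_sd, ar1 = ar1,
                 tr = tr, seed = as.integer(seed)),
            class = "bold_sim_spec")
}

#' Build a spherical beta blob
#'
#' Convenience for planting a spatially localized effect: `value` inside a
#' sphere, 0 outside.
#'
#' @param dims grid dimensions.
#' @param center sphere centre (voxel coordinates; default grid centre).
#' @param radius voxels.
#' @param value beta inside the blob.
#' @return 3-D array.
#' @export
beta_blob <- function(dims, center = NULL, radius = 3, value = 1) {
  if (is.null(center)) center <- (dims + 1) / 2
  ijk <- arrayInd(seq_len(prod(dims)), dims)
  dist2 <- (ijk[, 1] - center[1])^2 + (ijk[, 2] - center[2])^2 +
    (ijk[, 3] - center[3])^2
  array(ifelse(dist2 <= radius^2, value, 0), dims)
}

#' Simulate BOLD data from a design with planted betas
#'
#' Signal is `design %*% beta` per voxel with spatially varying planted
#' betas, plus AR(1) Gaussian noise (stationary, marginal SD `noise_sd`).
#' The ground-truth beta maps are returned for recovery tests.
#'
#' @param design a [build_design()] result or plain matrix.
#' @param spec a [bold_sim_spec()].
#' @param betas named list mapping regressor names to 3-D beta arrays (or
#'   scalars, meaning a constant map); unnamed regressors get beta 0.
#' @return list with `bold` (a [bold_dataset()]) and `truth` (list of beta
#'   arrays, one per regressor).
#' @export
generate_bold <- function(design, spec, betas = list()) {
  stopifnot(inherits(spec, "bold_sim_spec"))
  X <- if (inherits(design, "design_matrix")) design$matrix else
    as.matrix(design)
  tr <- if (inherits(design, "design_matrix")) design$tr else spec$tr
  d <- spec$dims
  nv <- prod(d)
  n_t <- nrow(X)
  B <- matrix(0, ncol(X), nv)
  truth <- vector("list", ncol(X))
  names(truth) <- colnames(X)
  for (nm in names(betas)) {
    if (!nm %in% colnames(X)) stop("unknown regressor in betas: ", nm)
    b <- betas[[nm]]
    arr <- if (length(b) == 1L) array(b, d) else as.array(b)
    if (!identical(dim(arr), d)) stop("beta map for ", nm,
                                      " has wrong dimensions")
    B[match(nm, colnames(X)), ] <- as.vector(arr)
  }
  for (j in seq_len(ncol(X)))
    truth[[j]] <- array(B[j, ], d)
  set.seed(spec$seed)
  signal <- X %*% B
  if (spec$noise_sd > 0) {
    innov_sd <- spec$noise_sd * sqrt(1 - spec$ar1^2)
    eps <- matrix(stats::rnorm(n_t * nv, sd = innov_sd), n_t, nv)
    if (spec$ar1 != 0) {
      eps[1, ] <- eps[1, ] / sqrt(1 - spec$ar1^2)
      for (t in 2:n_t) eps[t, ] <- spec$ar1 * eps[t - 1, ] + eps[t, ]
    }
    signal <- signal + eps
  }
  arr <- array(t(signal), c(d, n_t))
  list(bold = bold_dataset(arr, tr = tr), truth = truth)
}
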