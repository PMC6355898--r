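#' Normalize tokens for vocabulary lookup
#'
#' Lowercases, strips punctuation (everything except letters, digits and
#' internal apostrophes) and drops tokens that become empty.  The same
#' normalization is applied when a semantic space is trained and when it is
#' queried, so lookups are case- and punctuation-insensitive.  No stemming is
#' performed.
#'
#' @param tokens character vector of raw tokens.
#' @return character vector of normalized tokens (possibly shorter than the
#'   input when tokens reduce to the empty string).
#' @export
normalize_tokens <- function(tokens) {
  if (length(tokens) == 0L) return(character(0))
  x <- tolower(as.character(tokens))
  x <- gsub("[^[:alnum:]']+", "", x)
  x <- gsub("^'+|'+$", "", x)
  x[nzchar(x)]
}

#' Construct a training corpus
#'
#' A corpus is an ordered collection of tokenized documents used to train an
#' LSA semantic space.  Tokens are normalized with [normalize_tokens()].
#'
#' @param documents list of character vectors, one per document.
#' @param doc_ids optional character vector of document identifiers.
#' @return an object of class `corpus`: a list with elements `documents`
#'   and `doc_ids`.
#' @export
corpus <- function(documents, doc_ids = NULL) {
  if (!is.list(documents)) stop("`documents` must be a list of token vectors")
  if (length(documents) < 2L)
    stop("a corpus needs at least 2 documents, got ", length(documents))
  documents <- lapply(documents, normalize_tokens)
  empty <- vapply(documents, length, 1L) == 0L
  if (any(empty))
    stop("document(s) ", paste(which(empty), collapse = ", "),
         " are empty after token normalization")
  if (is.null(doc_ids)) doc_ids <- paste0("doc", seq_along(documents))
  if (length(doc_ids) != length(documents))
    stop("`doc_ids` length must match `documents`")
  structure(list(documents = documents, doc_ids = as.character(doc_ids)),
            class = "corpus")
}

#' Read a corpus from disk
#'
#' Two plain-text layouts are supported: a directory of UTF-8 `.txt` files
#' (one document per file) or a single file with one document per line.
#'
#' @param path directory or file path.
#' @return a [corpus()].
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (length(files) == 0L) stop("no .txt files found in ", path)
    docs <- lapply(files, function(f)
      unlist(strsplit(paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                            collapse = " "), "[[:space:]]+")))
    return(corpus(docs, doc_ids = basename(files)))
  }
  if (!file.exists(path)) stop("path does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  corpus(lapply(lines, function(l) unlist(strsplit(l, "[[:space:]]+"))))
}

#' @export
print.corpus <- function(x, ...) {
  cat("Corpus:", length(x$documents), "documents,",
      length(unique(unlist(x$documents))), "distinct tokens\n")
  invisible(x)
}

## term-document count matrix (terms in rows); dense is fine at the corpus
## sizes this package trains (synthetic / desk-scale spaces)
term_document_matrix <- function(corp) {
  vocab <- sort(unique(unlist(corp$documents)))
  m <- matrix(0, nrow = length(vocab), ncol = length(corp$documents),
              dimnames = list(vocab, corp$doc_ids))
  for (j in seq_along(corp$documents)) {
    tab <- table(corp$documents[[j]])
    m[names(tab), j] <- as.numeric(tab)
  }
  m
}

## log-entropy weighting, the standard LSA scheme: local weight log2(1+tf),
## global weight 1 + sum_j p_ij log2 p_ij / log2 n  (in [0,1]; 0 for a term
## spread evenly over every document)
log_entropy_weight <- function(tdm) {
  n_docs <- ncol(tdm)
  gf <- rowSums(tdm)
  p <- tdm / gf
  plogp <- ifelse(p > 0, p * log2(p), 0)
  global <- 1 + rowSums(plogp) / log2(n_docs)
  local <- log2(1 + tdm)
  list(weighted = local * global, global = global)
}

#' Build an LSA semantic space
#'
#' Forms the term-document count matrix of the corpus, applies term
#' weighting (log-entropy by default), and takes the rank-`k` truncated
#' singular value decomposition.  Word vectors are the left singular vectors
#' scaled by the singular values, so that dot products between words
#' approximate the weighted term co-occurrence structure.  The sign of each
#' component is fixed by forcing its largest-magnitude term loading to be
#' positive; cosines are unaffected but serialization becomes reproducible.
#'
#' @param corp a [corpus()].
#' @param k embedding dimensionality (positive integer).  Must not exceed the
#'   rank bound `min(|vocabulary|, n_documents)` after frequency filtering.
#' @param min_doc_freq drop terms occurring in fewer than this many documents.
#' @param weighting `"log-entropy"` (default) or `"raw"` (unweighted counts).
#' @return an object of class `semantic_space` with elements `vocabulary`
#'   (token -> row index), `vectors` (|V| x k matrix), `k`, `global_weights`,
#'   `singular_values` and `weighting`.
#' @export
build_space <- function(corp, k, min_doc_freq = 1L,
                        weighting = c("log-entropy", "raw")) {
  stopifnot(inherits(corp, "corpus"))
  weighting <- match.arg(weighting)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("`k` must be a positive integer")
  tdm <- term_document_matrix(corp)
  if (min_doc_freq > 1L) {
    keep <- rowSums(tdm > 0) >= min_doc_freq
    tdm <- tdm[keep, , drop = FALSE]
  }
  if (nrow(tdm) == 0L)
    stop("empty vocabulary after frequency filtering (min_doc_freq = ",
         min_doc_freq, ")")
  if (weighting == "log-entropy") {
    w <- log_entropy_weight(tdm)
    ## terms whose global weight vanishes carry no discriminative signal and
    ## would produce all-zero vector rows: drop them from the vocabulary
    keep <- w$global > 1e-12
    weighted <- w$weighted[keep, , drop = FALSE]
    global <- w$global[keep]
  } else {
    weighted <- tdm
    global <- rep(1, nrow(tdm))
    names(global) <- rownames(tdm)
  }
  if (nrow(weighted) == 0L) stop("all terms reduced to zero weight")
  rank_bound <- min(dim(weighted))
  if (k > rank_bound)
    stop("k = ", k, " exceeds the rank bound ", rank_bound,
         " of the weighted term-document matrix")
  sv <- svd(weighted, nu = k, nv = k)
  u <- sv$u
  d <- sv$d[seq_len(k)]
  ## sign convention: largest-|loading| entry of each component positive
  for (c in seq_len(k)) {
    i <- which.max(abs(u[, c]))
    if (u[i, c] < 0) u[, c] <- -u[, c]
  }
  vectors <- u * rep(d, each = nrow(u))
  rownames(vectors) <- rownames(weighted)
  vocab <- seq_len(nrow(vectors))
  names(vocab) <- rownames(weighted)
  structure(list(vocabulary = vocab, vectors = vectors, k = as.integer(k),
                 global_weights = global, singular_values = d,
                 weighting = weighting),
            class = "semantic_space")
}

#' @export
print.semantic_space <- function(x, ...) {
  cat("LSA semantic space: |V| =", length(x$vocabulary),
      " k =", x$k, " weighting =", x$weighting, "\n")
  invisible(x)
}

#' Look up the vector of one word
#'
#' The query token receives the same normalization as training tokens, so a
#' token differing only in case or punctuation from a vocabulary entry
#' resolves to that entry.  Out-of-vocabulary words return `NULL`, a marker
#' distinguishable from any real vector (never a zero vector).
#'
#' @param space a [build_space()] result.
#' @param token a single word.
#' @return numeric length-`k` vector, or `NULL` if the word is unknown.
#' @export
word_vector <- function(space, token) {
  stopifnot(inherits(space, "semantic_space"))
  tok <- normalize_tokens(token)
  if (length(tok) != 1L) return(NULL)
  i <- space$vocabulary[tok]
  if (is.na(i)) return(NULL)
  space$vectors[i, ]
}

#' Represent a passage as a vector
#'
#' The passage vector is the unweighted mean of the vectors of its
#' in-vocabulary words (a bag-of-words combination, invariant to word
#' order).  When no word of the passage is in the vocabulary the result is
#' flagged undefined rather than silently returned as a zero vector.
#'
#' @param space a [build_space()] result.
#' @param tokens character vector of words (non-empty).
#' @return an object of class `passage_vector`: list with `values`
#'   (length-`k` numeric, `NA` when undefined), `n_contributing` (count of
#'   in-vocabulary tokens) and `defined` (logical).
#' @export
passage_vector <- function(space, tokens) {
  stopifnot(inherits(space, "semantic_space"))
  toks <- normalize_tokens(tokens)
  if (length(toks) == 0L) stop("`tokens` must contain at least one word")
  idx <- space$vocabulary[toks]
  idx <- idx[!is.na(idx)]
  n <- length(idx)
  if (n == 0L) {
    values <- rep(NA_real_, space$k)
  } else if (n == 1L) {
    values <- space$vectors[idx, ]
  } else {
    values <- colMeans(space$vectors[idx, , drop = FALSE])
  }
  structure(list(values = unname(values), n_contributing = n,
                 defined = n > 0L),
            class = "passage_vector")
}

#' Cosine similarity between two vectors
#'
#' Standard cosine: symmetric and invariant to positive rescaling of either
#' argument.  The result is clamped to `[-1, 1]` to absorb floating-point
#' round-off.  Zero-norm or undefined inputs are an error, never a silent 0.
#'
#' @param u,v numeric vectors or [passage_vector()] objects.
#' @return a number in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (inherits(u, "passage_vector")) {
    if (!u$defined) stop("undefined passage vector (no in-vocabulary words)")
    u <- u$values
  }
  if (inherits(v, "passage_vector")) {
    if (!v$defined) stop("undefined passage vector (no in-vocabulary words)")
    v <- v$values
  }
  if (length(u) != length(v)) stop("vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vectors")
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Serialize a semantic space to a two-file plain-text format
#'
#' Writes `<prefix>_vocab.tsv` (token, row index, global weight) and
#' `<prefix>_vectors.tsv` (dense k-column matrix).  Numbers are written with
#' 17 significant digits so the round trip through [read_space()] is
#' bit-exact.
#'
#' @param space a `semantic_space`.
#' @param prefix file path prefix.
#' @return invisibly, the two file paths.
#' @export
write_space <- function(space, prefix) {
  stopifnot(inherits(space, "semantic_space"))
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  vocab_path <- paste0(prefix, "_vocab.tsv")
  vec_path <- paste0(prefix, "_vectors.tsv")
  vdf <- data.frame(token = names(space$vocabulary),
                    index = as.integer(space$vocabulary),
                    global_weight = fmt(space$global_weights),
                    stringsAsFactors = FALSE)
  utils::write.table(vdf, vocab_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hdr <- paste(c(paste0("# k=", space$k),
                 paste0("# weighting=", space$weighting),
                 paste0("# singular_values=",
                        paste(fmt(space$singular_values), collapse = ","))),
               collapse = "\n")
  con <- file(vec_path, "w", encoding = "UTF-8")
  writeLines(hdr, con)
  utils::write.table(matrix(fmt(space$vectors), nrow = nrow(space$vectors)),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(c(vocab_path, vec_path))
}

#' Read a serialized semantic space
#'
#' @param prefix the prefix passed to [write_space()].
#' @return a `semantic_space`.
#' @export
read_space <- function(prefix) {
  vocab_path <- paste0(prefix, "_vocab.tsv")
  vec_path <- paste0(prefix, "_vectors.tsv")
  vdf <- utils::read.table(vocab_path, sep = "\t", header = TRUE,
                           quote = "", comment.char = "",
                           colClasses = c("character", "integer", "numeric"))
  lines <- readLines(vec_path, encoding = "UTF-8")
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  getfield <- function(key) sub(paste0("^# ", key, "="), "",
                                hdr[startsWith(hdr, paste0("# ", key, "="))])
  k <- as.integer(getfield("k"))
  weighting <- getfield("weighting")
  d <- as.numeric(strsplit(getfield("singular_values"), ",")[[1]])
  vecs <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  ord <- order(vdf$index)
  vdf <- vdf[ord, ]
  rownames(vecs) <- vdf$token
  vocab <- vdf$index
  names(vocab) <- vdf$token
  gw <- vdf$global_weight
  names(gw) <- vdf$token
  structure(list(vocabulary = vocab, vectors = vecs, k = k,
                 global_weights = gw, singular_values = d,
                 weighting = weighting),
            class = "semantic_space")
}
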