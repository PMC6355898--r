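#' Lexical norms lookup table
#'
#' Bundles the per-word lexical norms (frequency, concreteness, age of
#' acquisition, semantic diversity, phoneme length) with the closed-class
#' word list and the noun list used to decide which tokens the noun means
#' are averaged over.  All words are normalized with [normalize_tokens()],
#' matching the semantic-space lookup convention.
#'
#' @param norms data.frame with columns `word`, `frequency`, `concreteness`,
#'   `age_of_acquisition`, `semantic_diversity`, `phoneme_length`.
#' @param closed_class character vector of closed-class (function) words.
#' @param nouns character vector of words treated as nouns.
#' @return an object of class `norms_table`.
#' @export
norms_table <- function(norms, closed_class, nouns) {
  req <- c("word", "frequency", "concreteness", "age_of_acquisition",
           "semantic_diversity", "phoneme_length")
  missing_cols <- setdiff(req, names(norms))
  if (length(missing_cols) > 0)
    stop("norms table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  norms$word <- normalize_tokens(as.character(norms$word))
  num <- norms[setdiff(req, "word")]
  if (any(!vapply(num, is.numeric, TRUE)) ||
      any(!is.finite(as.matrix(num))))
    stop("norm values must be finite numerics")
  if (anyDuplicated(norms$word)) stop("duplicated words in norms table")
  rownames(norms) <- norms$word
  structure(list(norms = norms,
                 closed_class = unique(normalize_tokens(closed_class)),
                 nouns = unique(normalize_tokens(nouns))),
            class = "norms_table")
}

#' Read a norms table from delimited text
#'
#' Expects a TSV of norms plus one-word-per-line closed-class and noun list
#' files.
#'
#' @param norms_path TSV with the columns documented in [norms_table()].
#' @param closed_class_path,nouns_path one word per line.
#' @return a [norms_table()].
#' @export
read_norms <- function(norms_path, closed_class_path, nouns_path) {
  norms <- utils::read.delim(norms_path, stringsAsFactors = FALSE)
  cc <- readLines(closed_class_path, warn = FALSE)
  nn <- readLines(nouns_path, warn = FALSE)
  norms_table(norms, cc[nzchar(cc)], nn[nzchar(nn)])
}

#' Speech characteristics of one block
#'
#' Computes, for the words produced in one 5-s block: the word count, the
#' type:token ratio (distinct / total), the proportion of closed-class
#' words, and the mean frequency, concreteness, age of acquisition, semantic
#' diversity and phoneme length of the nouns produced.  Noun means are
#' averaged over token occurrences (with multiplicity) of listed nouns that
#' have norm entries; when the block contains none they are `NA`.
#'
#' @param block_tokens character vector of the block's words.
#' @param norms a [norms_table()].
#' @return one-row data.frame with columns `n_words`, `type_token_ratio`,
#'   `closed_class_proportion`, `noun_frequency`, `noun_concreteness`,
#'   `noun_aoa`, `noun_semantic_diversity`, `noun_phoneme_length`.
#' @export
block_measures <- function(block_tokens, norms) {
  stopifnot(inherits(norms, "norms_table"))
  toks <- normalize_tokens(block_tokens)
  if (length(toks) == 0L)
    return(data.frame(n_words = NA_integer_, type_token_ratio = NA_real_,
                      closed_class_proportion = NA_real_,
                      noun_frequency = NA_real_, noun_concreteness = NA_real_,
                      noun_aoa = NA_real_, noun_semantic_diversity = NA_real_,
                      noun_phoneme_length = NA_real_))
  n <- length(toks)
  nouns <- toks[toks %in% norms$nouns & toks %in% norms$norms$word]
  noun_mean <- function(col) {
    if (length(nouns) == 0L) NA_real_ else mean(norms$norms[nouns, col])
  }
  data.frame(n_words = n,
             type_token_ratio = length(unique(toks)) / n,
             closed_class_proportion = mean(toks %in% norms$closed_class),
             noun_frequency = noun_mean("frequency"),
             noun_concreteness = noun_mean("concreteness"),
             noun_aoa = noun_mean("age_of_acquisition"),
             noun_semantic_diversity = noun_mean("semantic_diversity"),
             noun_phoneme_length = noun_mean("phoneme_length"))
}

#' Correlation structure of the block-level speech measures
#'
#' Pairwise-complete Pearson correlations between all numeric measure
#' columns, so blocks lacking noun norms still contribute to the pairs they
#' have values for.  Constant columns make a correlation undefined: those
#' entries are flagged `NA` (the diagonal stays 1) and a warning names the
#' columns rather than letting `NaN` propagate.
#'
#' @param block_table data.frame of block measures (e.g. rows of
#'   [block_measures()] plus coherence columns).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
measure_correlations <- function(block_table) {
  num <- block_table[vapply(block_table, is.numeric, TRUE)]
  if (ncol(num) < 2L) stop("need at least two numeric measure columns")
  complete_n <- vapply(num, function(x) sum(!is.na(x)), 1L)
  if (any(complete_n < 3L))
    stop("column(s) with fewer than 3 defined values: ",
         paste(names(num)[complete_n < 3L], collapse = ", "))
  const <- vapply(num, function(x) stats::sd(x, na.rm = TRUE) == 0, TRUE)
  r <- suppressWarnings(stats::cor(as.matrix(num),
                                   use = "pairwise.complete.obs"))
  if (any(const)) {
    warning("constant column(s) with undefined correlations: ",
            paste(names(num)[const], collapse = ", "))
    r[const, ] <- NA_real_
    r[, const] <- NA_real_
  }
  diag(r) <- 1
  r
}
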