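#' A single speech response
#'
#' One participant's transcribed answer to one prompt: an ordered word list
#' with optional word onset times.  When onsets are absent a uniform speech
#' rate over the production period is assumed.
#'
#' @param participant_id,prompt_id identifiers.
#' @param tokens ordered character vector of words (non-empty).
#' @param onsets optional numeric vector of word onsets in seconds from the
#'   start of the production period; must be non-decreasing and lie within
#'   `[0, period_length]`.
#' @param period_length length of the speech production period in seconds
#'   (default 50).
#' @return an object of class `response`.
#' @export
response <- function(participant_id, prompt_id, tokens, onsets = NULL,
                     period_length = 50) {
  tokens <- as.character(tokens)
  if (length(tokens) == 0L) stop("`tokens` must be non-empty")
  if (!is.null(onsets)) {
    onsets <- as.numeric(onsets)
    if (length(onsets) != length(tokens))
      stop("`onsets` must have one entry per token")
    if (any(diff(onsets) < 0)) stop("`onsets` must be non-decreasing")
    if (any(onsets < 0) || any(onsets > period_length))
      stop("`onsets` must lie within [0, period_length]")
  }
  structure(list(participant_id = as.character(participant_id),
                 prompt_id = as.character(prompt_id),
                 tokens = tokens, onsets = onsets,
                 period_length = period_length),
            class = "response")
}

#' @export
print.response <- function(x, ...) {
  cat("Response:", x$participant_id, "/", x$prompt_id, "-",
      length(x$tokens), "words over", x$period_length, "s\n")
  invisible(x)
}

#' Leave-one-out prototype vector for a prompt
#'
#' The prototype (composite) vector represents the typical semantic content
#' produced in response to a prompt.  It is the unweighted mean of the
#' passage vectors of all responses to the prompt *except* the one under
#' analysis, so a response never contributes to the standard it is scored
#' against.
#'
#' @param responses list of [response()] objects to the same prompt.
#' @param exclude participant identifier of the response under analysis.
#' @param space a [build_space()] semantic space.
#' @return an object of class `prototype_vector` with elements `prompt_id`,
#'   `values`, `n_responses_averaged` and `excluded`.
#' @export
prototype_vector <- function(responses, exclude, space) {
  stopifnot(is.list(responses), length(responses) >= 1L)
  prompt_ids <- unique(vapply(responses, function(r) r$prompt_id, ""))
  if (length(prompt_ids) != 1L)
    stop("all responses must address the same prompt; got: ",
         paste(prompt_ids, collapse = ", "))
  others <- Filter(function(r) r$participant_id != as.character(exclude),
                   responses)
  pvs <- lapply(others, function(r) passage_vector(space, r$tokens))
  pvs <- Filter(function(p) p$defined, pvs)
  if (length(pvs) == 0L)
    stop("no eligible responses to form a prototype for prompt ",
         prompt_ids, " (after excluding '", exclude, "')")
  if (length(pvs) == 1L)
    warning("prototype for prompt ", prompt_ids,
            " is based on a single response")
  mat <- do.call(rbind, lapply(pvs, `[[`, "values"))
  structure(list(prompt_id = prompt_ids, values = colMeans(mat),
                 n_responses_averaged = length(pvs),
                 excluded = as.character(exclude)),
            class = "prototype_vector")
}

## shared moving-window machinery: cumulative sums of word vectors give the
## window passage vector in O(1) per position
window_sums <- function(space, tokens) {
  toks <- vapply(as.character(tokens), function(t) {
    n <- normalize_tokens(t)
    if (length(n) == 1L) n else NA_character_
  }, "", USE.NAMES = FALSE)
  idx <- space$vocabulary[toks]
  known <- !is.na(idx)
  vecs <- matrix(0, nrow = length(toks), ncol = space$k)
  if (any(known)) vecs[known, ] <- space$vectors[idx[known], , drop = FALSE]
  cum <- apply(vecs, 2, cumsum)
  if (!is.matrix(cum)) cum <- matrix(cum, nrow = 1L)
  list(cum = cum, cum_n = cumsum(known))
}

## mean vector over token positions (from+1)..to, or NULL if none in vocab
window_mean <- function(ws, from, to) {
  n <- ws$cum_n[to] - if (from > 0) ws$cum_n[from] else 0
  if (n == 0) return(NULL)
  s <- ws$cum[to, ] - if (from > 0) ws$cum[from, ] else 0
  s / n
}

new_coherence_series <- function(resp, raw, window, type) {
  score <- ifelse(is.na(raw), NA_real_, 100 * pmax(0, raw))
  structure(list(participant_id = resp$participant_id,
                 prompt_id = resp$prompt_id,
                 word_index = seq_along(resp$tokens),
                 token = resp$tokens,
                 raw_cosine = raw, score = score,
                 window = as.integer(window), type = type),
            class = "coherence_series")
}

#' @export
print.coherence_series <- function(x, ...) {
  ok <- !is.na(x$score)
  cat(sprintf("%s coherence series: %d words, window %d, %d defined values",
              x$type, length(x$token), x$window, sum(ok)))
  if (any(ok)) cat(sprintf(", mean %.1f", mean(x$score[ok])))
  cat("\n")
  invisible(x)
}

#' Per-word global coherence of a response
#'
#' Moving-window global coherence: for each word from position `window`
#' onwards, a window of the current word and the `window - 1` preceding
#' words is represented as a passage vector and compared with the prompt's
#' leave-one-out prototype by cosine similarity.  The cosine is clamped at 0
#' from below and multiplied by 100, giving the reported 0-100 scale (100 =
#' speech semantically identical to the typical response, 0 = no semantic
#' relationship with the topic); the raw cosine is also retained.  The value
#' is assigned to the final word of the window; earlier words are undefined
#' (`NA`), as is any window containing no in-vocabulary word (logged).
#'
#' @param resp a [response()].
#' @param prototype a [prototype_vector()] for the same prompt.
#' @param space the semantic space used for both.
#' @param window window length in words (default 20).
#' @return a `coherence_series` with per-word `raw_cosine` and `score`.
#' @export
global_coherence_series <- function(resp, prototype, space, window = 20L) {
  stopifnot(inherits(resp, "response"), inherits(space, "semantic_space"))
  if (!inherits(prototype, "prototype_vector"))
    stop("`prototype` must be a prototype_vector")
  if (!is.numeric(window) || window < 1) stop("`window` must be >= 1")
  window <- as.integer(window)
  n <- length(resp$tokens)
  raw <- rep(NA_real_, n)
  if (n >= window) {
    ws <- window_sums(space, resp$tokens)
    n_oov <- 0L
    for (i in window:n) {
      m <- window_mean(ws, i - window, i)
      if (is.null(m)) { n_oov <- n_oov + 1L; next }
      raw[i] <- cosine_similarity(m, prototype$values)
    }
    if (n_oov > 0L)
      message("global coherence: ", n_oov,
              " window(s) with no in-vocabulary words left undefined")
  }
  new_coherence_series(resp, raw, window, "global")
}

#' Per-word local coherence of a response
#'
#' Local coherence captures how well adjoining stretches of speech relate to
#' one another: the window ending at the current word is compared with the
#' immediately preceding non-overlapping window of the same length.  Values
#' are on the same clamped 0-100 scale as global coherence and are undefined
#' for words before position `2 * window`.
#'
#' @inheritParams global_coherence_series
#' @return a `coherence_series`.
#' @export
local_coherence_series <- function(resp, space, window = 20L) {
  stopifnot(inherits(resp, "response"), inherits(space, "semantic_space"))
  if (!is.numeric(window) || window < 1) stop("`window` must be >= 1")
  window <- as.integer(window)
  n <- length(resp$tokens)
  raw <- rep(NA_real_, n)
  if (n >= 2L * window) {
    ws <- window_sums(space, resp$tokens)
    for (i in (2L * window):n) {
      cur <- window_mean(ws, i - window, i)
      prev <- window_mean(ws, i - 2L * window, i - window)
      if (is.null(cur) || is.null(prev)) next
      raw[i] <- cosine_similarity(cur, prev)
    }
  }
  new_coherence_series(resp, raw, window, "local")
}

## word -> 5-s block assignment: by onset when available, else a uniform
## rate of n_words / period_length; half-open intervals [start, end)
word_blocks <- function(resp, block_length) {
  n <- length(resp$tokens)
  onsets <- resp$onsets
  if (is.null(onsets)) onsets <- (seq_len(n) - 1) * resp$period_length / n
  n_blocks <- as.integer(ceiling(resp$period_length / block_length))
  blk <- pmin(floor(onsets / block_length) + 1L, n_blocks)
  list(block = as.integer(blk), n_blocks = n_blocks)
}

#' Block-level coherence of a response
#'
#' The production period is divided into fixed-length blocks (default 5 s)
#' and each block's coherence is the mean of the defined per-word values of
#' the words produced in it.  The first block has no reliable estimate (the
#' window reaches back before the response began), so it receives the second
#' block's value.  Any other block without defined word values receives the
#' value of the nearest later defined block (logged).
#'
#' @param series a [global_coherence_series()] (or local) result.
#' @param resp the [response()] the series was computed from.
#' @param block_length block duration in seconds (default 5).
#' @return data.frame with columns `block`, `value`, `n_words`,
#'   `n_defined_words`, `filled` (logical: value substituted from another
#'   block).
#' @export
block_coherence <- function(series, resp, block_length = 5) {
  stopifnot(inherits(series, "coherence_series"), inherits(resp, "response"))
  wb <- word_blocks(resp, block_length)
  if (wb$n_blocks < 2L)
    stop("response spans fewer than 2 blocks; block coherence undefined")
  value <- rep(NA_real_, wb$n_blocks)
  n_words <- tabulate(wb$block, nbins = wb$n_blocks)
  n_def <- integer(wb$n_blocks)
  for (b in seq_len(wb$n_blocks)) {
    v <- series$score[wb$block == b]
    v <- v[!is.na(v)]
    n_def[b] <- length(v)
    if (length(v) > 0) value[b] <- mean(v)
  }
  filled <- rep(FALSE, wb$n_blocks)
  ## fill undefined blocks (other than block 1) from the nearest later
  ## defined block; fall back to the nearest earlier one at the tail
  defined <- which(!is.na(value) & seq_len(wb$n_blocks) > 1L)
  if (length(defined) == 0L)
    stop("no block beyond the first has a defined coherence value")
  for (b in seq(2L, wb$n_blocks)) {
    if (is.na(value[b])) {
      later <- defined[defined > b]
      src <- if (length(later) > 0) later[1] else max(defined[defined < b])
      value[b] <- value[src]
      filled[b] <- TRUE
      message("block ", b, " has no defined word values; using block ",
              src, "'s value")
    }
  }
  ## first-block rule: use the second block's value
  value[1] <- value[2]
  filled[1] <- TRUE
  data.frame(block = seq_len(wb$n_blocks), value = value,
             n_words = n_words, n_defined_words = n_def, filled = filled)
}

#' Participant-level mean coherence
#'
#' Grand mean over the pooled block values of all of a participant's
#' responses (each block weighted equally), used as a second-level
#' individual-differences covariate.
#'
#' @param block_tables list of [block_coherence()] data frames (or a single
#'   one).
#' @return a single number.
#' @export
participant_mean_coherence <- function(block_tables) {
  if (is.data.frame(block_tables)) block_tables <- list(block_tables)
  stopifnot(length(block_tables) >= 1L)
  vals <- unlist(lapply(block_tables, function(b) b$value))
  mean(vals, na.rm = TRUE)
}
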