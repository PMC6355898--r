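#' Read speech transcripts from TSV
#'
#' The transcript format is a UTF-8 TSV with columns `participant_id`,
#' `prompt_id`, `word_index` (contiguous from 1 within participant x
#' prompt), `token`, and optionally `onset_s` and `run_id`.  Rows are
#' grouped into one [response()] per participant x prompt.
#'
#' @param path TSV file.
#' @param period_length production period length in seconds (default 50).
#' @return list of [response()] objects (empty, with a warning, for an
#'   empty file); `run_id` is attached as attribute `run` on each response.
#' @export
read_transcripts <- function(path, period_length = 50) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  req <- c("participant_id", "prompt_id", "word_index", "token")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop("transcript file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty transcript file: ", path)
    return(list())
  }
  df$word_index <- as.integer(df$word_index)
  key <- paste(df$participant_id, df$prompt_id, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    sub <- df[rows, ]
    ord <- order(sub$word_index)
    sub <- sub[ord, ]
    if (!identical(sub$word_index, seq_len(nrow(sub)))) {
      bad <- rows[ord][which(sub$word_index != seq_len(nrow(sub)))[1]]
      stop("non-contiguous word_index for participant '",
           sub$participant_id[1], "', prompt '", sub$prompt_id[1],
           "' at file row ", bad + 1L)
    }
    onsets <- if ("onset_s" %in% names(sub)) as.numeric(sub$onset_s) else NULL
    r <- response(sub$participant_id[1], sub$prompt_id[1], sub$token,
                  onsets = onsets, period_length = period_length)
    if ("run_id" %in% names(sub)) attr(r, "run") <- sub$run_id[1]
    out[[length(out) + 1L]] <- r
  }
  out
}

#' Write responses as a transcript TSV
#'
#' Lossless counterpart of [read_transcripts()].
#'
#' @param responses list of [response()] objects.
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_transcripts <- function(responses, path) {
  rows <- lapply(responses, function(r) {
    d <- data.frame(participant_id = r$participant_id,
                    prompt_id = r$prompt_id,
                    word_index = seq_along(r$tokens),
                    token = r$tokens, stringsAsFactors = FALSE)
    if (!is.null(r$onsets)) d$onset_s <- r$onsets
    if (!is.null(attr(r, "run"))) d$run_id <- attr(r, "run")
    d
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a BIDS-style events table
#'
#' TSV with columns `onset`, `duration`, `trial_type` and optionally `run`;
#' validated and converted to a [trial_timing()] table.
#'
#' @param path events TSV.
#' @return a `trial_timing` data.frame.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("onset", "duration", "trial_type")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop("events file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  trial_timing(df$trial_type, df$onset, df$duration,
               run = if ("run" %in% names(df)) df$run else 1L)
}

#' Pipeline configuration
#'
#' All tunable constants of the pipeline with their task defaults: 20-word
#' coherence window, 5-s blocks, 2-SD winsorization, 180-s high-pass,
#' voxelwise p 0.005 with 5000 cluster simulations, 30% atlas threshold
#' with a +/-30 mm medial cut, TR 2.2 s, 8-s planning / 50-s production /
#' 15-s automatic-speech periods.  Any override is logged.
#'
#' @param ... named overrides of the defaults.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(...) {
  cfg <- list(window_length = 20L, block_length = 5, winsor_sd = 2,
              highpass_cutoff = 180, voxel_p = 0.005, n_sim = 5000L,
              roi_threshold = 0.30, medial_cut_mm = 30, tr = 2.2,
              planning_duration = 8, production_duration = 50,
              baseline_duration = 15, lsa_k = 300L, min_doc_freq = 1L,
              microtime_resolution = 16L, microtime_onset = 8L,
              seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(over)) {
    message("config override: ", nm, " = ", over[[nm]],
            " (default ", cfg[[nm]], ")")
    cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

## 32-bit FNV-1a hash of a string, for run provenance
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    ## xor affects only the low byte since b < 256
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    ## 32-bit modular multiply via 16-bit halves to stay within double
    ## precision (16777619 = 0x01000193)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Score all responses and assemble block-level coherence tables
#'
#' For each response: leave-one-out prototype over the other responses to
#' the same prompt, per-word global (and local) coherence, and 5-s block
#' coherence.  The workhorse behind [run_pipeline()].
#'
#' @param responses list of [response()] objects (possibly several prompts).
#' @param space a [build_space()] semantic space.
#' @param window coherence window in words (default 20).
#' @param block_length seconds (default 5).
#' @param local also compute local coherence (default TRUE).
#' @return data.frame with one row per response x block: `participant_id`,
#'   `prompt_id`, `block`, `global_coherence`, `local_coherence` (if
#'   requested), `n_words`.
#' @export
score_responses <- function(responses, space, window = 20L,
                            block_length = 5, local = TRUE) {
  prompts <- vapply(responses, function(r) r$prompt_id, "")
  out <- list()
  for (i in seq_along(responses)) {
    r <- responses[[i]]
    pool <- responses[prompts == r$prompt_id]
    proto <- prototype_vector(pool, exclude = r$participant_id, space)
    gs <- global_coherence_series(r, proto, space, window)
    gb <- block_coherence(gs, r, block_length)
    row <- data.frame(participant_id = r$participant_id,
                      prompt_id = r$prompt_id, block = gb$block,
                      global_coherence = gb$value, n_words = gb$n_words)
    if (local) {
      ls <- local_coherence_series(r, space, window)
      lb <- tryCatch(block_coherence(ls, r, block_length),
                     error = function(e) NULL)
      row$local_coherence <- if (is.null(lb)) NA_real_ else lb$value
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}

#' Run the full synthetic-to-statistics pipeline
#'
#' End-to-end demonstration path on generated data: topic corpus ->
#' semantic space -> drifting responses -> per-word and block coherence ->
#' prepared coherence and time-in-trial modulators -> first-level design ->
#' simulated BOLD with a planted coherence effect -> GLM and coherence
#' contrast.  Writes the coherence table, design matrix, contrast maps
#' (NIfTI) and a JSON summary with config hash and seed manifest to
#' `out_dir`.  Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param topic_spec,drift generator specs (defaults:
#'   [topic_model_spec()] with 4 topics, [drift_spec()]).
#' @param n_participants responses per prompt (default 6).
#' @param bold_dims simulation grid (default `c(8, 8, 8)`).
#' @param coherence_beta planted amplitude of the coherence modulator
#'   (default 0.5, in a central blob).
#' @return invisibly, a list with the main intermediate objects
#'   (`space`, `coherence_table`, `design`, `fit`, `coherence_contrast`,
#'   `summary`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         topic_spec = topic_model_spec(),
                         drift = drift_spec(), n_participants = 6L,
                         bold_dims = c(8L, 8L, 8L), coherence_beta = 0.5) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  k <- min(config$lsa_k, 8L)

  corp <- generate_corpus(topic_spec, n_docs = 10L * topic_spec$n_topics,
                          seed = seed)
  space <- build_space(corp, k = k, min_doc_freq = config$min_doc_freq)
  responses <- generate_responses(topic_spec, prompt_topic = 1L, drift,
                                  n_participants = n_participants,
                                  seed = seed + 1L)
  coh <- score_responses(responses, space, window = config$window_length,
                         block_length = config$block_length)
  utils::write.table(coh, file.path(out_dir, "coherence_blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## one run per participant is overkill at desk scale: model participant 1
  target <- coh[coh$participant_id == coh$participant_id[1], ]
  n_trials <- 4L
  trial_gap <- 7
  plan_d <- config$planning_duration
  prod_d <- config$production_duration
  cycle <- plan_d + prod_d + trial_gap
  timings <- trial_timing(
    condition = rep(c("extended_planning", "extended_production"), n_trials),
    onset = as.vector(vapply(seq_len(n_trials) - 1L,
                             function(i) c(i * cycle, i * cycle + plan_d),
                             numeric(2))),
    duration = rep(c(plan_d, prod_d), n_trials))
  n_volumes <- ceiling((n_trials * cycle + 30) / config$tr)
  blocks_per_trial <- as.integer(prod_d / config$block_length)
  coh_values <- rep(target$global_coherence, length.out =
                      n_trials * blocks_per_trial)
  trial_ids <- rep(seq_len(n_trials), each = blocks_per_trial)
  coh_mod <- prepare_modulator(coh_values, run_ids = 1L,
                               trial_ids = trial_ids,
                               block = rep(seq_len(blocks_per_trial),
                                           n_trials),
                               winsor_sd = config$winsor_sd)
  time_mod <- prepare_modulator(rep(time_in_trial_covariate(
    prod_d, config$block_length), n_trials),
    run_ids = 1L, trial_ids = trial_ids,
    winsor_sd = config$winsor_sd)
  design <- build_design(timings,
                         modulators = list(coherence = coh_mod,
                                           time = time_mod),
                         n_volumes = n_volumes, tr = config$tr,
                         highpass_cutoff = config$highpass_cutoff,
                         block_length = config$block_length,
                         microtime_resolution = config$microtime_resolution,
                         microtime_onset = config$microtime_onset)
  write_design(design, file.path(out_dir, "design.tsv"))

  sim <- generate_bold(design,
                       bold_sim_spec(dims = bold_dims, seed = seed + 2L),
                       betas = list(
                         extended_production = 1,
                         coherence = beta_blob(bold_dims,
                                               value = coherence_beta)))
  fit <- fit_glm(sim$bold, design)
  con <- contrast(fit, c(coherence = 1))
  eff_map <- as_map(con, "effect")
  eff_map[is.na(eff_map)] <- 0
  img <- RNifti::asNifti(eff_map)
  RNifti::writeNifti(img, file.path(out_dir, "coherence_effect.nii.gz"))

  summary <- list(
    config = unclass(config),
    config_hash = fnv1a_hash(paste(names(config),
                                   vapply(config, paste, "",
                                          collapse = ","),
                                   collapse = ";")),
    seeds = list(corpus = seed, responses = seed + 1L, bold = seed + 2L),
    n_responses = length(responses),
    mean_global_coherence = mean(coh$global_coherence, na.rm = TRUE),
    coherence_contrast_mean_t = mean(con$t, na.rm = TRUE),
    planted_coherence_beta = coherence_beta)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(space = space, responses = responses,
                 coherence_table = coh, design = design, fit = fit,
                 coherence_contrast = con, summary = summary))
}
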