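#' Winsorize and mean-centre a parametric modulator
#'
#' Prepares a per-block modulator (coherence, time-in-trial, factor score)
#' for entry in the first-level model.  Within each scanning run, values
#' more than `winsor_sd` standard deviations from the run mean are clipped
#' to that bound (winsorized, bounds computed on the raw values), and the
#' series is then mean-centred so each run is exactly zero-mean.  A run with
#' zero variance is centred only, with a warning.  Re-preparing an already
#' prepared series is a no-op.
#'
#' @param values numeric vector of raw block values, or a `modulator_series`
#'   (returned unchanged).
#' @param run_ids run identifier per value (default: one run).
#' @param trial_ids optional trial identifier per value (needed by
#'   [shift_modulator()]).
#' @param block optional within-trial block index per value.
#' @param winsor_sd winsorization bound in SD units (default 2).
#' @return an object of class `modulator_series`: data.frame with columns
#'   `run_id`, `trial_id`, `block`, `value`, `raw`, plus attributes
#'   `n_winsorized`, `centered`, `winsorized`.
#' @export
prepare_modulator <- function(values, run_ids = 1L, trial_ids = NULL,
                              block = NULL, winsor_sd = 2) {
  if (inherits(values, "modulator_series")) {
    message("modulator already prepared; returning unchanged")
    return(values)
  }
  values <- as.numeric(values)
  n <- length(values)
  if (any(!is.finite(values))) stop("modulator values must be finite")
  run_ids <- rep_len(run_ids, n)
  if (is.null(trial_ids)) trial_ids <- rep(1L, n)
  if (is.null(block)) block <- stats::ave(seq_len(n),
                                          paste(run_ids, trial_ids),
                                          FUN = seq_along)
  out <- rep(NA_real_, n)
  n_wins <- 0L
  for (r in unique(run_ids)) {
    sel <- run_ids == r
    if (sum(sel) < 2L)
      stop("run ", r, " has fewer than 2 blocks")
    v <- values[sel]
    m <- mean(v); s <- stats::sd(v)
    if (s == 0) {
      warning("run ", r, " modulator has zero variance; centering only")
      out[sel] <- v - m
      next
    }
    lo <- m - winsor_sd * s
    hi <- m + winsor_sd * s
    clipped <- pmin(pmax(v, lo), hi)
    n_wins <- n_wins + sum(clipped != v)
    out[sel] <- clipped - mean(clipped)
  }
  structure(data.frame(run_id = run_ids, trial_id = trial_ids,
                       block = as.integer(block), value = out, raw = values),
            class = c("modulator_series", "data.frame"),
            n_winsorized = n_wins, centered = TRUE, winsorized = TRUE,
            winsor_sd = winsor_sd)
}

#' Shift a modulator in time by whole blocks
#'
#' Builds the "early" (`shift = -1`) and "late" (`shift = +1`) variants of a
#' parametric modulator, in which each block's value is assigned to the
#' preceding or following block: under an early shift the value carried by
#' block 4 appears at block 3, under a late shift at block 5.  Shifting
#' never crosses a trial boundary; the block left vacant at a trial edge
#' receives its nearest within-trial neighbour's value (logged once).  The
#' shift is pure reindexing — re-prepare afterwards if exact zero-mean is
#' required.
#'
#' @param series a `modulator_series` from [prepare_modulator()].
#' @param shift integer number of blocks, typically -1 (early) or +1 (late).
#' @return a `modulator_series` with shifted `value`.
#' @export
shift_modulator <- function(series, shift) {
  stopifnot(inherits(series, "modulator_series"))
  if (!is.numeric(shift) || shift != round(shift) || shift == 0)
    stop("`shift` must be a nonzero whole number of blocks")
  shift <- as.integer(shift)
  out <- series
  n_filled <- 0L
  key <- paste(series$run_id, series$trial_id)
  for (tr in unique(key)) {
    sel <- which(key == tr)
    ord <- sel[order(series$block[sel])]
    nb <- length(ord)
    if (abs(shift) >= nb)
      stop("|shift| = ", abs(shift), " >= ", nb,
           " blocks in trial ", tr)
    v <- series$value[ord]
    ## value of source block b appears at block b + shift
    newv <- rep(NA_real_, nb)
    src <- seq_len(nb) - shift
    ok <- src >= 1L & src <= nb
    newv[ok] <- v[src[ok]]
    for (b in which(!ok)) {
      nb_def <- which(ok)
      nearest <- nb_def[which.min(abs(nb_def - b))]
      newv[b] <- newv[nearest]
      n_filled <- n_filled + 1L
    }
    out$value[ord] <- newv
  }
  if (n_filled > 0L)
    message("shift_modulator: ", n_filled,
            " trial-edge block(s) filled with nearest within-trial value")
  out
}

#' Time-within-trial covariate
#'
#' The raw block index (1..n) within a speech production period, used as the
#' second parametric modulator (tracking activation change over the 50-s
#' period).  Prepare per run with [prepare_modulator()] like any modulator.
#'
#' @param duration production period length in seconds (default 50).
#' @param block_length block duration in seconds (default 5).
#' @return integer vector `1:(duration/block_length)`.
#' @export
time_in_trial_covariate <- function(duration = 50, block_length = 5) {
  n <- duration / block_length
  if (n != round(n)) stop("duration must be a multiple of block_length")
  seq_len(as.integer(n))
}

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities: a positive response peaking ~5-6 s
#' after the event and an undershoot peaking ~15-16 s, with a 1:6
#' peak-to-undershoot amplitude ratio, truncated at 32 s.
#'
#' @param t time in seconds (vector).
#' @param peak_delay,undershoot_delay gamma shape parameters (6, 16).
#' @param peak_disp,undershoot_disp gamma scale parameters (1, 1).
#' @param ratio peak/undershoot amplitude ratio (6).
#' @param duration truncation length in seconds (32).
#' @return hrf values at `t` (0 outside `[0, duration]`).
#' @export
canonical_hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                          peak_disp = 1, undershoot_disp = 1, ratio = 6,
                          duration = 32) {
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                  scale = undershoot_disp) / ratio
  h[t < 0 | t > duration] <- 0
  h
}

#' Convolve a microtime stimulus series with the canonical HRF
#'
#' The stimulus (boxcar or modulated boxcar) is represented on a microtime
#' grid of `microtime_resolution` bins per TR, convolved with the canonical
#' double-gamma HRF (normalized to unit sum on the grid, so a sustained unit
#' boxcar plateaus at 1), and sampled at microtime bin `microtime_onset`
#' (0-based) of each volume.
#'
#' @param x stimulus values on the microtime grid (length
#'   `n_volumes * microtime_resolution`).
#' @param tr repetition time in seconds.
#' @param microtime_resolution bins per TR (default 16).
#' @param microtime_onset 0-based sampling bin within each volume (default
#'   8, the middle of the TR).
#' @param hrf_params optional named list passed to [canonical_hrf()].
#' @return numeric vector of length `n_volumes`.
#' @export
hrf_convolve <- function(x, tr, microtime_resolution = 16L,
                         microtime_onset = 8L, hrf_params = list()) {
  mtr <- as.integer(microtime_resolution)
  if (tr <= 0) stop("`tr` must be positive")
  if (length(x) %% mtr != 0L)
    stop("length(x) must be a multiple of microtime_resolution")
  n_vol <- length(x) %/% mtr
  dt <- tr / mtr
  tgrid <- seq(0, 32, by = dt)
  h <- do.call(canonical_hrf, c(list(t = tgrid), hrf_params))
  h <- h / sum(h)
  conv <- stats::convolve(x, rev(h), type = "open")[seq_along(x)]
  conv[(seq_len(n_vol) - 1L) * mtr + microtime_onset + 1L]
}

## boxcar (possibly amplitude-modulated) on the microtime grid of one run
microtime_boxcar <- function(onsets, durations, amplitudes, n_volumes, tr,
                             mtr) {
  dt <- tr / mtr
  x <- numeric(n_volumes * mtr)
  run_end <- n_volumes * tr
  for (i in seq_along(onsets)) {
    if (durations[i] < 0) stop("negative event duration")
    if (onsets[i] >= run_end) next
    from <- floor(onsets[i] / dt) + 1L
    to <- min(ceiling((onsets[i] + durations[i]) / dt), length(x))
    x[from:to] <- x[from:to] + amplitudes[i]
  }
  x
}

#' Discrete cosine drift basis
#'
#' High-pass filtering is implemented within the GLM as a discrete cosine
#' transform basis: `K = floor(2 * run_length / cutoff)` regressors per run,
#' removing fluctuations slower than the cutoff period.
#'
#' @param n_volumes volumes in the run.
#' @param tr repetition time in seconds.
#' @param cutoff high-pass cutoff period in seconds (default 180).
#' @return matrix `n_volumes` x `K` (possibly 0 columns).
#' @export
dct_drift_basis <- function(n_volumes, tr, cutoff = 180) {
  K <- floor(2 * n_volumes * tr / cutoff)
  t <- seq_len(n_volumes) - 1L
  if (K < 1L) return(matrix(0, n_volumes, 0))
  b <- sapply(seq_len(K), function(k)
    cos(pi * k * (2 * t + 1) / (2 * n_volumes)))
  colnames(b) <- paste0("dct", seq_len(K))
  b
}

#' Event timing table
#'
#' Validates a trial timing table for design construction.  Conditions
#' follow the four-event task structure: extended speech planning (8-s
#' prompt display), extended speech production (50-s period, modelled as
#' concatenated 5-s blocks), automatic speech planning and automatic
#' (nursery-rhyme) production (15 s).
#'
#' @param condition character vector of condition labels.
#' @param onset,duration numeric vectors in seconds (onsets relative to run
#'   start).
#' @param run run identifier per event.
#' @return data.frame of class `trial_timing`.
#' @export
trial_timing <- function(condition, onset, duration, run = 1L) {
  if (any(onset < 0)) stop("onsets must be non-negative")
  if (any(duration <= 0)) stop("durations must be positive")
  structure(data.frame(condition = as.character(condition),
                       onset = as.numeric(onset),
                       duration = as.numeric(duration),
                       run = rep_len(run, length(onset))),
            class = c("trial_timing", "data.frame"))
}

## 5-s block onsets of every production event, in (run, trial, block) order
production_blocks <- function(timings, condition = "extended_production",
                              block_length = 5) {
  ev <- timings[timings$condition == condition, , drop = FALSE]
  ev <- ev[order(ev$run, ev$onset), , drop = FALSE]
  if (nrow(ev) == 0L) return(NULL)
  out <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    nb <- as.integer(ceiling(ev$duration[i] / block_length))
    data.frame(run = ev$run[i], trial = i, block = seq_len(nb),
               onset = ev$onset[i] + (seq_len(nb) - 1) * block_length,
               duration = pmin(block_length,
                               ev$duration[i] - (seq_len(nb) - 1) *
                                 block_length))
  }))
  out
}

#' Build the first-level design matrix
#'
#' Assembles, per run and concatenated across runs: one HRF-convolved
#' boxcar regressor per condition; one regressor per parametric modulator
#' (the production-period 5-s blocks, each block's boxcar scaled by its
#' prepared modulator value, then convolved); the per-volume nuisance
#' columns supplied (motion parameters and externally computed noise
#' components); a discrete-cosine drift basis implementing the 180-s
#' high-pass cutoff; and a per-run intercept.  Deterministic: identical
#' inputs give a bit-identical matrix.
#'
#' @param timings a [trial_timing()] table.
#' @param modulators named list of `modulator_series` (from
#'   [prepare_modulator()]), one value per production block in (run, trial,
#'   block) order.
#' @param nuisance optional per-volume data.frame/matrix (rows =
#'   total volumes across runs).
#' @param n_volumes volumes per run (scalar or one per run).
#' @param tr repetition time in seconds (default 2.2).
#' @param highpass_cutoff seconds (default 180; `NULL` disables drift
#'   columns).
#' @param modulated_condition condition whose blocks carry the modulators
#'   (default `"extended_production"`).
#' @param block_length seconds (default 5).
#' @param microtime_resolution,microtime_onset see [hrf_convolve()].
#' @param hrf_params optional named list passed to [canonical_hrf()].
#' @return an object of class `design_matrix`: list with `matrix` (volumes x
#'   regressors), `names`, `run` (per row), `tr`, `task_columns` (indices of
#'   condition + modulator regressors).
#' @export
build_design <- function(timings, modulators = list(), nuisance = NULL,
                         n_volumes, tr = 2.2, highpass_cutoff = 180,
                         modulated_condition = "extended_production",
                         block_length = 5,
                         microtime_resolution = 16L, microtime_onset = 8L,
                         hrf_params = list()) {
  stopifnot(inherits(timings, "trial_timing"))
  runs <- if (nrow(timings) == 0L) 1L else sort(unique(timings$run))
  n_volumes <- rep_len(n_volumes, length(runs))
  mtr <- as.integer(microtime_resolution)
  conditions <- unique(timings$condition)
  pb <- production_blocks(timings, modulated_condition, block_length)
  if (length(modulators) > 0) {
    if (is.null(pb)) stop("modulators supplied but no '",
                          modulated_condition, "' events")
    for (nm in names(modulators)) {
      if (nrow(modulators[[nm]]) != nrow(pb))
        stop("modulator '", nm, "' has ", nrow(modulators[[nm]]),
             " values but the design has ", nrow(pb),
             " production blocks")
    }
  }
  cols <- list(); col_names <- character(0); run_of_row <- integer(0)
  blocks_per_run <- lapply(seq_along(runs), function(ri)
    if (is.null(pb)) NULL else pb[pb$run == runs[ri], , drop = FALSE])
  ## task regressors, per run then stacked
  task <- NULL
  for (cond in conditions) {
    reg <- numeric(0)
    for (ri in seq_along(runs)) {
      ev <- timings[timings$condition == cond & timings$run == runs[ri], ]
      run_end <- n_volumes[ri] * tr
      if (nrow(ev) > 0 && any(ev$onset + ev$duration > run_end))
        warning("event(s) in condition '", cond, "' run ", runs[ri],
                " extend past scan end; truncated")
      x <- microtime_boxcar(ev$onset, ev$duration,
                            rep(1, nrow(ev)), n_volumes[ri], tr, mtr)
      reg <- c(reg, hrf_convolve(x, tr, mtr, microtime_onset, hrf_params))
    }
    task <- cbind(task, reg)
    col_names <- c(col_names, cond)
  }
  for (nm in names(modulators)) {
    mod <- modulators[[nm]]
    reg <- numeric(0)
    offset <- 0L
    for (ri in seq_along(runs)) {
      bl <- blocks_per_run[[ri]]
      nb <- if (is.null(bl)) 0L else nrow(bl)
      amps <- mod$value[offset + seq_len(nb)]
      offset <- offset + nb
      x <- if (nb > 0)
        microtime_boxcar(bl$onset, bl$duration, amps, n_volumes[ri], tr, mtr)
      else numeric(n_volumes[ri] * mtr)
      reg <- c(reg, hrf_convolve(x, tr, mtr, microtime_onset, hrf_params))
    }
    task <- cbind(task, reg)
    col_names <- c(col_names, nm)
  }
  n_task <- length(col_names)
  ## nuisance
  X <- task
  if (!is.null(nuisance)) {
    nuis <- as.matrix(nuisance)
    if (nrow(nuis) != sum(n_volumes))
      stop("nuisance table has ", nrow(nuis), " rows; expected ",
           sum(n_volumes))
    nn <- colnames(nuis)
    if (is.null(nn)) nn <- paste0("nuisance", seq_len(ncol(nuis)))
    X <- cbind(X, nuis)
    col_names <- c(col_names, nn)
  }
  ## drift + intercept, block-diagonal by run
  total <- sum(n_volumes)
  row_run <- rep(runs, n_volumes)
  if (!is.null(highpass_cutoff)) {
    for (ri in seq_along(runs)) {
      b <- dct_drift_basis(n_volumes[ri], tr, highpass_cutoff)
      if (ncol(b) == 0L) next
      full <- matrix(0, total, ncol(b))
      full[row_run == runs[ri], ] <- b
      X <- cbind(X, full)
      col_names <- c(col_names,
                     paste0("run", runs[ri], "_", colnames(b)))
    }
  }
  for (ri in seq_along(runs)) {
    X <- cbind(X, as.numeric(row_run == runs[ri]))
    col_names <- c(col_names, paste0("run", runs[ri], "_intercept"))
  }
  colnames(X) <- col_names
  zero_task <- which(apply(X[, seq_len(n_task), drop = FALSE], 2,
                           function(c) all(c == 0)))
  zero_mod <- setdiff(col_names[zero_task], names(modulators))
  if (length(zero_mod) > 0)
    warning("all-zero task regressor(s): ", paste(zero_mod, collapse = ", "))
  structure(list(matrix = X, names = col_names, run = row_run, tr = tr,
                 task_columns = seq_len(n_task),
                 production_blocks = pb),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("Design matrix:", nrow(x$matrix), "volumes x", ncol(x$matrix),
      "regressors (TR =", x$tr, "s)\n")
  cat("  task:", paste(x$names[x$task_columns], collapse = ", "), "\n")
  invisible(x)
}

#' Write a design matrix as TSV
#' @param design a `design_matrix`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_design <- function(design, path) {
  df <- as.data.frame(design$matrix)
  df <- cbind(run = design$run, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
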