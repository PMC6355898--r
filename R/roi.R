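#' Build a region of interest from a probabilistic atlas
#'
#' Voxels with probability strictly greater than the threshold (default
#' 30%) enter the mask; a probability of exactly 0.30 is excluded.  For
#' regions like pars orbitalis, whose atlas extent reaches into medial
#' prefrontal cortex, an optional medial cut removes every voxel with
#' `|x| < medial_cut_mm` in world coordinates.
#'
#' @param prob_atlas 3-D array of probabilities in `[0, 1]` (or an RNifti
#'   image, whose world transform supplies the x coordinates).
#' @param threshold inclusion threshold, strict (default 0.30).
#' @param medial_cut_mm drop voxels with `|x| <` this (mm); `NULL` disables.
#' @param voxel_size voxel edge lengths in mm, used to derive x coordinates
#'   when `prob_atlas` is a plain array (default 2 mm isotropic).
#' @param origin voxel index (1-based, can be fractional) at world x = 0;
#'   default: grid centre.
#' @param name ROI label, e.g. `"L-BA45"`.
#' @return object of class `roi`: `mask` (logical array), `name`,
#'   `provenance`.
#' @export
roi_build <- function(prob_atlas, threshold = 0.30, medial_cut_mm = 30,
                      voxel_size = c(2, 2, 2), origin = NULL,
                      name = "custom") {
  arr <- as.array(prob_atlas)
  d <- dim(arr)
  if (length(d) != 3L) stop("`prob_atlas` must be 3-D")
  mask <- arr > threshold
  x_mm <- NULL
  if (!is.null(medial_cut_mm)) {
    if (inherits(prob_atlas, "niftiImage")) {
      xf <- RNifti::xform(prob_atlas)
      ijk <- arrayInd(seq_len(prod(d)), d) - 1L
      x_mm <- array(xf[1, 1] * ijk[, 1] + xf[1, 2] * ijk[, 2] +
                      xf[1, 3] * ijk[, 3] + xf[1, 4], d)
    } else {
      if (is.null(origin)) origin <- (d[1] + 1) / 2
      x_mm <- array(rep((seq_len(d[1]) - origin) * voxel_size[1],
                        times = d[2] * d[3]), d)
    }
    mask <- mask & abs(x_mm) >= medial_cut_mm
  }
  if (!any(mask))
    stop("ROI '", name, "' is empty after thresholding",
         if (!is.null(medial_cut_mm)) " and medial cut" else "")
  structure(list(mask = mask, name = name,
                 provenance = list(threshold = threshold,
                                   medial_cut_mm = medial_cut_mm,
                                   n_voxels = sum(mask))),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat("ROI", x$name, "-", sum(x$mask), "voxels (threshold >",
      x$provenance$threshold,
      if (!is.null(x$provenance$medial_cut_mm))
        paste0(", medial cut |x| < ", x$provenance$medial_cut_mm, " mm"),
      ")\n")
  invisible(x)
}

#' Summarize a statistic map over an ROI
#'
#' Unweighted mean of the map's values over the ROI voxels, giving the
#' participant-level scalar used in ROI group analyses.
#'
#' @param map 3-D array (e.g. from [as_map()]) on the ROI grid.
#' @param roi a [roi_build()] result.
#' @return a single number.
#' @export
roi_effect <- function(map, roi) {
  stopifnot(inherits(roi, "roi"))
  map <- as.array(map)
  if (!identical(dim(map), dim(roi$mask)))
    stop("map grid ", paste(dim(map), collapse = "x"),
         " does not match ROI grid ",
         paste(dim(roi$mask), collapse = "x"))
  mean(map[roi$mask])
}

#' Effects at quantile levels of a block parameter
#'
#' Splits the speech blocks into `n_bins` near-equal sets by their parameter
#' value (1st bin = lowest values; ties broken by stable block order), fits
#' one HRF-convolved regressor per bin alongside any baseline columns, and
#' reports each bin's effect relative to the overall (block-count-weighted)
#' mean speech-related activation.
#'
#' @param y numeric time series (e.g. ROI-averaged BOLD), or time x voxel
#'   matrix.
#' @param blocks data.frame with columns `onset`, `duration`, `value` (the
#'   ranking parameter) for each speech block, onsets relative to the start
#'   of `y`.
#' @param tr repetition time in seconds.
#' @param n_bins number of sets (default 5, i.e. quintiles).
#' @param nuisance optional per-volume covariate table.
#' @param microtime_resolution,microtime_onset see [hrf_convolve()].
#' @return data.frame with one row per bin: `bin`, `n_blocks`, `effect`,
#'   `relative_effect`, plus attribute `overall_mean`.
#' @export
quintile_effects <- function(y, blocks, tr, n_bins = 5L, nuisance = NULL,
                             microtime_resolution = 16L,
                             microtime_onset = 8L) {
  Y <- if (is.matrix(y)) y else matrix(y, ncol = 1L)
  nb <- nrow(blocks)
  if (nb < n_bins)
    stop("need at least ", n_bins, " blocks, got ", nb)
  ord <- order(blocks$value, seq_len(nb))  # stable tie-break
  bin <- integer(nb)
  bin[ord] <- ceiling(seq_len(nb) * n_bins / nb)
  n_vol <- nrow(Y)
  mtr <- as.integer(microtime_resolution)
  X <- sapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    x <- microtime_boxcar(blocks$onset[sel], blocks$duration[sel],
                          rep(1, sum(sel)), n_vol, tr, mtr)
    hrf_convolve(x, tr, mtr, microtime_onset)
  })
  colnames(X) <- paste0("bin", seq_len(n_bins))
  if (!is.null(nuisance)) X <- cbind(X, as.matrix(nuisance))
  X <- cbind(X, intercept = 1)
  fit <- fit_glm(Y, X)
  betas <- fit$beta[seq_len(n_bins), 1]
  counts <- tabulate(bin, n_bins)
  overall <- sum(betas * counts) / sum(counts)
  out <- data.frame(bin = seq_len(n_bins), n_blocks = counts,
                    effect = unname(betas),
                    relative_effect = unname(betas - overall))
  attr(out, "overall_mean") <- overall
  out
}

#' Repeated-measures 2x2 ANCOVA on ROI effects
#'
#' Two within-participant factors with two levels each (hemisphere: left vs
#' right; region: BA45 vs BA47) and an optional between-participant
#' covariate (mean scan-to-scan displacement).  Each effect is tested on
#' the corresponding within-participant difference score regressed on an
#' intercept plus the centred covariate, giving F with df
#' `(1, n - 1 - n_covariates)`.
#'
#' @param roi_effects data.frame with columns `participant`, `hemisphere`
#'   (`"left"`/`"right"`), `region` (`"BA45"`/`"BA47"`), `value`; one row
#'   per cell, complete 2x2 per participant.
#' @param covariate optional numeric vector, one value per participant (in
#'   the participant order of `sort(unique(participant))`).
#' @return data.frame with rows `hemisphere`, `region`,
#'   `hemisphere:region`: columns `F`, `df1`, `df2`, `p`.
#' @export
anova_2x2 <- function(roi_effects, covariate = NULL) {
  req <- c("participant", "hemisphere", "region", "value")
  if (!all(req %in% names(roi_effects)))
    stop("roi_effects needs columns: ", paste(req, collapse = ", "))
  ids <- sort(unique(as.character(roi_effects$participant)))
  n <- length(ids)
  cell <- function(p, h, r) {
    v <- roi_effects$value[roi_effects$participant == p &
                             roi_effects$hemisphere == h &
                             roi_effects$region == r]
    if (length(v) != 1L)
      stop("participant ", p, " is missing (or duplicates) cell ",
           h, "/", r)
    v
  }
  L45 <- vapply(ids, cell, 0, h = "left", r = "BA45")
  L47 <- vapply(ids, cell, 0, h = "left", r = "BA47")
  R45 <- vapply(ids, cell, 0, h = "right", r = "BA45")
  R47 <- vapply(ids, cell, 0, h = "right", r = "BA47")
  contrasts <- list(
    hemisphere = ((L45 + L47) - (R45 + R47)) / 2,
    region = ((L45 + R45) - (L47 + R47)) / 2,
    `hemisphere:region` = (L45 - L47) - (R45 - R47))
  if (!is.null(covariate)) {
    if (length(covariate) != n)
      stop("covariate must have one value per participant (", n, ")")
    X <- cbind(1, covariate - mean(covariate))
  } else {
    X <- matrix(1, n, 1)
  }
  df2 <- n - ncol(X)
  out <- do.call(rbind, lapply(names(contrasts), function(nm) {
    d <- contrasts[[nm]]
    b <- solve(crossprod(X), crossprod(X, d))
    res <- d - X %*% b
    s2 <- sum(res^2) / df2
    se <- sqrt(s2 * chol2inv(chol(crossprod(X)))[1, 1])
    Fv <- if (se > 0) (b[1] / se)^2 else ifelse(b[1] == 0, 0, Inf)
    data.frame(effect = nm, F = Fv, df1 = 1, df2 = df2,
               p = stats::pf(Fv, 1, df2, lower.tail = FALSE))
  }))
  rownames(out) <- out$effect
  out
}
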