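#' A 4-D BOLD dataset
#'
#' Container pairing a 4-D functional image with a brain mask and the TR.
#' Data may be supplied as an in-memory array or read from NIfTI with
#' [read_bold()].
#'
#' @param data 4-D numeric array (x, y, z, volume).
#' @param mask logical/0-1 3-D array on the same grid (default: all voxels).
#' @param tr repetition time in seconds.
#' @return object of class `bold_dataset`.
#' @export
bold_dataset <- function(data, mask = NULL, tr = 2.2) {
  d <- dim(data)
  if (length(d) != 4L) stop("`data` must be a 4-D array")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!identical(dim(mask), d[1:3]))
    stop("mask grid ", paste(dim(mask), collapse = "x"),
         " does not match image grid ", paste(d[1:3], collapse = "x"))
  structure(list(data = data, mask = array(as.logical(mask), d[1:3]),
                 tr = tr),
            class = "bold_dataset")
}

#' Read a BOLD dataset from NIfTI files
#' @param bold_path 4-D NIfTI image.
#' @param mask_path optional binary NIfTI mask on the same grid.
#' @param tr TR in seconds; if `NULL`, taken from the NIfTI header.
#' @return a [bold_dataset()].
#' @export
read_bold <- function(bold_path, mask_path = NULL, tr = NULL) {
  img <- RNifti::readNifti(bold_path)
  if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
  mask <- if (is.null(mask_path)) NULL else
    array(as.array(RNifti::readNifti(mask_path)) > 0,
          dim(img)[1:3])
  bold_dataset(as.array(img), mask, tr)
}

## time x voxel matrix of the masked voxels
masked_timeseries <- function(bold) {
  d <- dim(bold$data)
  m <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
  t(m[as.vector(bold$mask), , drop = FALSE])
}

#' Fit the voxelwise general linear model
#'
#' Ordinary least squares of every masked voxel's time series on the design
#' matrix.  A rank-deficient design is fitted through the Moore-Penrose
#' pseudo-inverse with a warning naming the dependent columns; residual
#' degrees of freedom are `n_volumes - rank(design)`.
#'
#' @param data a [bold_dataset()], or a numeric time x voxel matrix (a plain
#'   vector is treated as a single voxel).
#' @param design a [build_design()] result or a plain numeric matrix.
#' @return object of class `glm_fit`: `beta` (regressor x voxel),
#'   `sigma2` (residual variance per voxel), `df`, `xtx_inv`, `rank`,
#'   `mask`/`dims` when fitted from a `bold_dataset`.
#' @export
fit_glm <- function(data, design) {
  X <- if (inherits(design, "design_matrix")) design$matrix else
    as.matrix(design)
  mask <- NULL; dims <- NULL
  if (inherits(data, "bold_dataset")) {
    Y <- masked_timeseries(data)
    mask <- data$mask; dims <- dim(data$data)[1:3]
  } else {
    Y <- as.matrix(data)
  }
  if (nrow(Y) != nrow(X))
    stop("data has ", nrow(Y), " volumes but design has ", nrow(X), " rows")
  if (any(!is.finite(Y))) stop("masked voxels contain non-finite values")
  qrx <- qr(X)
  r <- qrx$rank
  if (r < ncol(X)) {
    dep <- colnames(X)[qrx$pivot[-seq_len(r)]]
    warning("design is rank-deficient (rank ", r, " of ", ncol(X),
            "); dependent column(s): ", paste(dep, collapse = ", "),
            "; using pseudo-inverse")
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    pinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    beta <- pinv %*% Y
    xtx_inv <- tcrossprod(pinv)
  } else {
    beta <- qr.coef(qrx, Y)
    xtx_inv <- chol2inv(chol(crossprod(X)))
  }
  res <- Y - X %*% beta
  df <- nrow(X) - r
  sigma2 <- if (df > 0) colSums(res^2) / df else rep(NA_real_, ncol(Y))
  rownames(beta) <- colnames(X)
  structure(list(beta = beta, sigma2 = sigma2, df = df,
                 xtx_inv = xtx_inv, rank = r, n_volumes = nrow(X),
                 regressors = colnames(X), mask = mask, dims = dims),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("GLM fit:", ncol(x$beta), "voxel(s),", nrow(x$beta),
      "regressors, df =", x$df, "\n")
  invisible(x)
}

#' Linear contrast of GLM parameters
#'
#' Effect `w'beta` and its t statistic per voxel.  Where the standard error
#' is zero the t map is `Inf` with the sign of the effect (flagged, not
#' `NaN`).
#'
#' @param fit a [fit_glm()] result.
#' @param weights numeric contrast vector (length = number of regressors) or
#'   a named vector/list giving nonzero weights by regressor name.
#' @return object of class `contrast_result`: `effect`, `se`, `t`,
#'   `weights`, `df`.
#' @export
contrast <- function(fit, weights) {
  stopifnot(inherits(fit, "glm_fit"))
  p <- nrow(fit$beta)
  if (!is.null(names(weights)) && length(weights) < p) {
    w <- stats::setNames(rep(0, p), fit$regressors)
    unknown <- setdiff(names(weights), fit$regressors)
    if (length(unknown) > 0)
      stop("unknown regressor(s): ", paste(unknown, collapse = ", "))
    w[names(weights)] <- unlist(weights)
  } else {
    w <- as.numeric(weights)
    if (length(w) != p)
      stop("contrast has ", length(w), " weights but the model has ",
           p, " regressors")
  }
  effect <- drop(crossprod(w, fit$beta))
  var_w <- drop(t(w) %*% fit$xtx_inv %*% w)
  se <- sqrt(fit$sigma2 * var_w)
  t <- ifelse(se > 0, effect / se,
              ifelse(effect == 0, 0, sign(effect) * Inf))
  structure(list(effect = effect, se = se, t = t, weights = w,
                 df = fit$df, mask = fit$mask, dims = fit$dims),
            class = "contrast_result")
}

#' Rebuild a 3-D statistic map from masked voxel values
#'
#' @param x a `contrast_result` (or `glm_fit` with `which` a regressor
#'   name), or a plain vector with `mask` supplied.
#' @param statistic `"effect"`, `"t"` or `"se"` for contrast results.
#' @param mask logical 3-D array (taken from the object when present).
#' @return 3-D array with `NA` outside the mask.
#' @export
as_map <- function(x, statistic = "effect", mask = NULL) {
  if (inherits(x, "contrast_result")) {
    vals <- x[[statistic]]
    mask <- x$mask
  } else vals <- x
  if (is.null(mask)) stop("no mask available to rebuild the map")
  out <- array(NA_real_, dim(mask))
  out[mask] <- vals
  out
}

#' Mean scan-to-scan displacement
#'
#' Summary of a participant's propensity to move: the mean absolute change
#' between successive volumes is computed for each of the six realignment
#' parameters, and these six means are averaged.  Used as a second-level
#' nuisance covariate.
#'
#' @param motion_params volumes x parameters numeric table.
#' @return a single number.
#' @export
mean_displacement <- function(motion_params) {
  m <- as.matrix(motion_params)
  if (nrow(m) < 2L) stop("need at least 2 volumes")
  mean(colMeans(abs(diff(m))))
}

#' Second-level one-sample model across participants
#'
#' Fits, per voxel, the participant contrast estimates on an intercept plus
#' mean-centred covariates (e.g. mean scan-to-scan displacement, mean
#' coherence).  The intercept t is the one-sample group test; each
#' covariate's slope t tests individual differences.  Zero residual
#' variance yields an `Inf`-flagged t, not `NaN`.
#'
#' @param maps participants x voxels matrix (or a vector: one voxel per
#'   participant... i.e. a single-voxel/ROI analysis).
#' @param covariates optional data.frame/matrix, one row per participant.
#' @return object of class `second_level_result`: `t`, `effect`, `se`
#'   matrices (term x voxel), `df`, `terms`.
#' @export
second_level <- function(maps, covariates = NULL) {
  Y <- if (is.matrix(maps)) maps else matrix(maps, ncol = 1L)
  n <- nrow(Y)
  if (n < 3L) stop("need at least 3 participants")
  X <- matrix(1, n, 1L, dimnames = list(NULL, "intercept"))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (nrow(cv) != n) stop("covariates must have one row per participant")
    cv <- scale(cv, center = TRUE, scale = FALSE)
    if (is.null(colnames(cv)))
      colnames(cv) <- paste0("covariate", seq_len(ncol(cv)))
    X <- cbind(X, cv)
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("collinear covariates: design rank ", qrx$rank, " < ", ncol(X))
  beta <- qr.coef(qrx, Y)
  res <- Y - X %*% beta
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  ## residuals that vanish to round-off are true zero variance (flagged Inf t)
  sigma2[sigma2 <= 1e-12 * pmax(colMeans(Y^2), .Machine$double.xmin)] <- 0
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(outer(diag(xtx_inv), sigma2))
  t <- ifelse(se > 0, beta / se,
              ifelse(beta == 0, 0, sign(beta) * Inf))
  dimnames(beta) <- dimnames(se) <- dimnames(t) <-
    list(colnames(X), colnames(Y))
  structure(list(effect = beta, se = se, t = t, df = df,
                 terms = colnames(X)),
            class = "second_level_result")
}

#' @export
print.second_level_result <- function(x, ...) {
  cat("Second-level model:", ncol(x$effect), "voxel(s), terms:",
      paste(x$terms, collapse = ", "), "; df =", x$df, "\n")
  invisible(x)
}
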