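#' Latent factor decomposition of the speech measures
#'
#' Principal components analysis of the standardized block-by-measure table.
#' Components with eigenvalues greater than one (Kaiser criterion) are
#' retained and obliquely rotated (varimax followed by promax, the
#' Hendrickson-White convention) to aid interpretation; the explained
#' variance fraction is reported on the unrotated components.  The fitting
#' sample's column means and standard deviations are stored so new blocks
#' can be scored on the same scale.
#'
#' @param block_table numeric data.frame/matrix of block measures; rows with
#'   missing values are dropped (with a message).
#' @param rotation `"promax"` (default) or `"none"`.
#' @param kappa promax power (conventional default 4).
#' @return an object of class `factor_model`: `loadings` (pattern matrix,
#'   measures x factors), `n_factors`, `rotation`,
#'   `explained_variance_fraction`, `factor_correlations`, `eigenvalues`,
#'   plus standardization (`center`, `scale`) and the fitted correlation
#'   matrix.
#' @export
extract_factors <- function(block_table, rotation = c("promax", "none"),
                            kappa = 4) {
  rotation <- match.arg(rotation)
  x <- as.matrix(block_table[vapply(block_table, is.numeric, TRUE)])
  cc <- stats::complete.cases(x)
  if (!all(cc)) {
    message("dropping ", sum(!cc), " incomplete row(s) before factor ",
            "extraction")
    x <- x[cc, , drop = FALSE]
  }
  p <- ncol(x)
  if (nrow(x) < p + 1L)
    stop("need at least ", p + 1L, " complete rows for ", p, " measures")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0))
    stop("constant column(s): ", paste(colnames(x)[scl == 0], collapse = ", "))
  z <- scale(x, center = ctr, scale = scl)
  R <- stats::cor(x)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    qrx <- qr(z)
    dep <- colnames(x)[qrx$pivot[-seq_len(qrx$rank)]]
    stop("measure table is rank-deficient; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
  nf <- sum(ev$values > 1)
  if (nf < 1L) nf <- 1L
  L <- ev$vectors[, seq_len(nf), drop = FALSE] *
    rep(sqrt(ev$values[seq_len(nf)]), each = p)
  for (c in seq_len(nf)) {
    i <- which.max(abs(L[, c]))
    if (L[i, c] < 0) L[, c] <- -L[, c]
  }
  rownames(L) <- colnames(x)
  if (rotation == "promax" && nf > 1L) {
    vm <- stats::varimax(L, normalize = TRUE)
    pm <- stats::promax(unclass(vm$loadings), m = kappa)
    U <- vm$rotmat %*% pm$rotmat
    pattern <- unclass(vm$loadings) %*% pm$rotmat
    phi <- solve(crossprod(U))
    dimnames(phi) <- list(paste0("F", seq_len(nf)), paste0("F", seq_len(nf)))
  } else {
    pattern <- L
    U <- diag(nf)
    phi <- diag(nf)
    dimnames(phi) <- list(paste0("F", seq_len(nf)), paste0("F", seq_len(nf)))
  }
  colnames(pattern) <- paste0("F", seq_len(nf))
  structure(list(loadings = pattern, unrotated_loadings = L,
                 n_factors = nf, rotation = rotation, rotmat = U,
                 explained_variance_fraction =
                   sum(ev$values[seq_len(nf)]) / p,
                 factor_correlations = phi, eigenvalues = ev$values,
                 center = ctr, scale = scl, correlation = R,
                 columns = colnames(x)),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("Factor model: %d factor(s) (%s rotation), %.1f%% variance\n",
              x$n_factors, x$rotation,
              100 * x$explained_variance_fraction))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Score blocks on a fitted factor model
#'
#' Regression-method factor scores: new rows are standardized with the
#' fitting sample's means/SDs and projected through
#' `W = R^-1 (Lambda Phi)` (the structure matrix), so the scores of the
#' fitted rows have mean zero per factor.
#'
#' @param model a [extract_factors()] result.
#' @param block_table table with exactly the columns the model was fitted on
#'   (same names and order).
#' @return matrix of scores, one row per input row (`NA` rows for incomplete
#'   inputs).
#' @export
factor_scores <- function(model, block_table) {
  stopifnot(inherits(model, "factor_model"))
  x <- as.matrix(block_table[vapply(block_table, is.numeric, TRUE)])
  if (!identical(colnames(x), model$columns))
    stop("column mismatch: model was fitted on [",
         paste(model$columns, collapse = ", "), "], got [",
         paste(colnames(x), collapse = ", "), "]")
  z <- scale(x, center = model$center, scale = model$scale)
  W <- solve(model$correlation,
             model$loadings %*% model$factor_correlations)
  scores <- z %*% W
  colnames(scores) <- colnames(model$loadings)
  scores
}

#' Tucker congruence coefficient
#'
#' Cosine-type similarity between two loading vectors, used to compare a
#' recovered factor with a planted one (1 = identical up to positive
#' scaling; sign-ambiguous factors compare via `abs()`).
#'
#' @param a,b numeric vectors of equal length.
#' @return a number in `[-1, 1]`.
#' @export
tucker_congruence <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Match recovered factors to reference factors
#'
#' Factor order and sign after extraction are arbitrary; this finds the
#' column permutation of `recovered` maximizing the mean absolute Tucker
#' congruence with `reference` (exhaustive over permutations, fine for the
#' handful of factors used here).
#'
#' @param recovered,reference loading matrices with equal dimensions.
#' @return list with `order` (permutation of recovered columns),
#'   `congruence` (per matched pair, absolute value) and `mean_congruence`.
#' @export
match_factors <- function(recovered, reference) {
  stopifnot(ncol(recovered) == ncol(reference),
            nrow(recovered) == nrow(reference))
  nf <- ncol(recovered)
  C <- abs(crossprod(
    apply(recovered, 2, function(v) v / sqrt(sum(v^2))),
    apply(reference, 2, function(v) v / sqrt(sum(v^2)))))
  perms <- all_permutations(nf)
  best <- NULL; best_val <- -Inf
  for (p in perms) {
    val <- mean(C[cbind(p, seq_len(nf))])
    if (val > best_val) { best_val <- val; best <- p }
  }
  list(order = best, congruence = C[cbind(best, seq_len(nf))],
       mean_congruence = best_val)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
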