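#' Gaussian smoothing of a 3-D field
#'
#' Separable Gaussian convolution implemented in the Fourier domain with
#' circular boundary conditions, so smoothing a stationary white-noise field
#' yields a stationary smooth field (no edge attenuation) — the property the
#' Monte-Carlo null simulation relies on.
#'
#' @param x 3-D numeric array.
#' @param fwhm_vox full width at half maximum in voxel units (scalar or
#'   length 3); values `<= 0` leave the axis unsmoothed.
#' @return smoothed array of the same dimensions.
#' @export
gaussian_smooth3d <- function(x, fwhm_vox) {
  d <- dim(x)
  if (length(d) != 3L) stop("`x` must be a 3-D array")
  fwhm_vox <- rep_len(fwhm_vox, 3L)
  k1 <- lapply(seq_len(3L), function(a) {
    n <- d[a]
    if (fwhm_vox[a] <= 0) return(c(1, numeric(n - 1L)))
    sigma <- fwhm_vox[a] / (2 * sqrt(2 * log(2)))
    pos <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-pos^2 / (2 * sigma^2))
    k / sum(k)
  })
  kern <- outer(outer(k1[[1]], k1[[2]]), k1[[3]])
  dim(kern) <- d
  Re(fft(fft(x) * fft(kern), inverse = TRUE)) / prod(d)
}

## neighbour offsets for 6- or 26-connectivity
connectivity_offsets <- function(connectivity) {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1L, ]
  as.matrix(offs)
}

#' Label connected clusters of suprathreshold voxels
#'
#' Flood-fill labelling of `TRUE` voxels under 26-connectivity
#' (face/edge/corner neighbours; the convention of common Monte-Carlo
#' cluster tools) or 6-connectivity.
#'
#' @param supra logical 3-D array.
#' @param connectivity 26 (default) or 6.
#' @return list with `labels` (integer array, 0 = background) and `sizes`
#'   (voxel count per cluster, possibly empty).
#' @export
label_clusters <- function(supra, connectivity = 26L) {
  d <- dim(supra)
  if (length(d) != 3L) stop("`supra` must be a 3-D logical array")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  offs <- connectivity_offsets(connectivity)
  labels <- array(0L, d)
  idx <- which(supra)
  sizes <- integer(0)
  if (length(idx) == 0L) return(list(labels = labels, sizes = sizes))
  coords <- arrayInd(idx, d)
  lookup <- array(0L, d); lookup[idx] <- seq_along(idx)
  visited <- logical(length(idx))
  for (s in seq_along(idx)) {
    if (visited[s]) next
    lab <- length(sizes) + 1L
    stack <- s; visited[s] <- TRUE; count <- 0L
    while (length(stack) > 0L) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      count <- count + 1L
      labels[idx[cur]] <- lab
      cc <- coords[cur, ]
      for (o in seq_len(nrow(offs))) {
        nx <- cc[1] + offs[o, 1]; ny <- cc[2] + offs[o, 2]
        nz <- cc[3] + offs[o, 3]
        if (nx < 1L || ny < 1L || nz < 1L ||
            nx > d[1] || ny > d[2] || nz > d[3]) next
        nb <- lookup[nx, ny, nz]
        if (nb > 0L && !visited[nb]) {
          visited[nb] <- TRUE
          stack <- c(stack, nb)
        }
      }
    }
    sizes <- c(sizes, count)
  }
  list(labels = labels, sizes = sizes)
}

#' Monte-Carlo cluster-extent threshold
#'
#' Determines the minimum cluster size controlling the family-wise error of
#' suprathreshold clusters at corrected p < 0.05.  Each simulation draws a
#' Gaussian white-noise field on the mask's grid, smooths it to the stated
#' FWHM, standardizes it empirically within the mask, thresholds at the
#' voxelwise p (one-tailed by default, matching directional t contrasts;
#' `tail = "two"` thresholds `|z|`), and records the largest suprathreshold
#' cluster.  The minimum cluster size is the 95th percentile of the
#' max-cluster-size distribution plus one — the smallest extent whose
#' simulated family-wise false-positive rate is at most 0.05.
#'
#' @param mask logical 3-D array defining the analysed volume.
#' @param fwhm smoothness of the noise fields, FWHM in mm.
#' @param voxel_size voxel edge length in mm (scalar or length 3).
#' @param voxel_p voxelwise type-1 error rate (default 0.005).
#' @param n_sim number of simulations (default 5000; fewer than 100 warns).
#' @param seed RNG seed.
#' @param tail `"one"` (default) or `"two"`.
#' @param connectivity cluster connectivity, 26 (default) or 6.
#' @return object of class `cluster_threshold`: `min_cluster_size`,
#'   `max_cluster_sizes` (the simulated distribution), plus the parameters.
#' @export
cluster_threshold_montecarlo <- function(mask, fwhm, voxel_size = 1,
                                         voxel_p = 0.005, n_sim = 5000L,
                                         seed = 1L, tail = c("one", "two"),
                                         connectivity = 26L) {
  tail <- match.arg(tail)
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("mask is empty")
  voxel_size <- rep_len(voxel_size, 3L)
  if (fwhm < max(voxel_size))
    stop("smoothness (", fwhm, " mm) must be at least the voxel size")
  if (n_sim < 100L)
    warning("n_sim < 100 gives an unstable extent percentile")
  d <- dim(mask)
  fwhm_vox <- fwhm / voxel_size
  ## fwhm equal to the voxel size means an unsmoothed (independent) field
  fwhm_vox[fwhm_vox <= 1] <- 0
  zthr <- if (tail == "one") stats::qnorm(1 - voxel_p) else
    stats::qnorm(1 - voxel_p / 2)
  set.seed(seed)
  maxes <- integer(n_sim)
  for (s in seq_len(n_sim)) {
    noise <- array(stats::rnorm(prod(d)), d)
    sm <- if (any(fwhm_vox > 0)) gaussian_smooth3d(noise, fwhm_vox) else noise
    v <- sm[mask]
    z <- (sm - mean(v)) / stats::sd(v)
    supra <- if (tail == "one") z > zthr else abs(z) > zthr
    supra <- supra & mask
    cl <- label_clusters(supra, connectivity)
    maxes[s] <- if (length(cl$sizes) > 0) max(cl$sizes) else 0L
  }
  k <- as.integer(stats::quantile(maxes, 0.95, type = 1) + 1)
  structure(list(min_cluster_size = max(k, 1L),
                 max_cluster_sizes = maxes, voxel_p = voxel_p,
                 fwhm = fwhm, voxel_size = voxel_size, n_sim = n_sim,
                 tail = tail, connectivity = connectivity, seed = seed),
            class = "cluster_threshold")
}

#' @export
print.cluster_threshold <- function(x, ...) {
  cat(sprintf(paste0("Cluster-extent threshold: >= %d voxels (voxel p = %g",
                     ", FWHM = %g mm, %d simulations, %s-tailed)\n"),
              x$min_cluster_size, x$voxel_p, x$fwhm, x$n_sim, x$tail))
  invisible(x)
}
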