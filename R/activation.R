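#' Isotropic Gaussian spatial smoothing
#'
#' Convolves each 3D volume with an isotropic Gaussian of
#' `sd = fwhm / (2 * sqrt(2 * log(2)))` mm, converted to voxels. The kernel
#' is applied separably per axis with boundary renormalization (the kernel
#' mass falling outside the volume is redistributed), so a constant volume
#' stays constant. `fwhm_mm = 0` is the identity.
#'
#' @param scan A [subject_scan()] or a 3D/4D numeric array.
#' @param fwhm_mm Full width at half maximum in mm (>= 0).
#' @param voxel_size_mm Voxel size, required when `scan` is a bare array.
#' @return Same type as the input.
#' @export
smooth_volume <- function(scan, fwhm_mm, voxel_size_mm = NULL) {
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) stop("`fwhm_mm` must be >= 0")
  if (inherits(scan, "subject_scan")) {
    out <- scan
    out$data <- smooth_array(scan$data, fwhm_mm, scan$voxel_size_mm)
    return(out)
  }
  if (is.null(voxel_size_mm))
    stop("`voxel_size_mm` is required for a bare array")
  smooth_array(scan, fwhm_mm, voxel_size_mm)
}

smooth_array <- function(arr, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm == 0) return(arr)
  sd_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  d <- dim(arr)
  for (axis in 1:3) arr <- conv_axis(arr, smooth_matrix(d[axis], sd_vox), axis)
  arr
}

# row-normalized banded Gaussian convolution matrix: boundary mass is
# renormalized so a constant stays constant
smooth_matrix <- function(n, sd_vox) {
  W <- stats::dnorm(outer(seq_len(n), seq_len(n), `-`), sd = sd_vox)
  W[abs(row(W) - col(W)) > max(1, ceiling(4 * sd_vox))] <- 0
  W / rowSums(W)
}

# apply an n x n operator along one spatial axis of a 3D/4D array
conv_axis <- function(arr, W, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  x <- aperm(arr, perm)
  dp <- dim(x)
  x <- W %*% matrix(x, nrow = d[axis])
  dim(x) <- dp
  aperm(x, order(perm))
}

#' Remove per-voxel linear trends
#'
#' Subtracts the least-squares linear fit (intercept restored) from every
#' voxel time series, as a minimal drift correction.
#'
#' @param scan A [subject_scan()].
#' @return A `subject_scan` with detrended data.
#' @export
detrend_scan <- function(scan) {
  stopifnot(inherits(scan, "subject_scan"))
  d <- dim(scan$data)
  nt <- d[4]
  X <- scan_matrix(scan)                  # voxels x time
  t0 <- seq_len(nt) - (nt + 1) / 2        # centered time
  slope <- (X %*% t0) / sum(t0^2)
  out <- scan
  out$data <- array(X - slope %*% t0, dim = d)
  out
}

#' Voxel-wise task cross-correlation statistics
#'
#' Pearson correlation of every voxel time series with the expected BOLD
#' regressor, and the two-sided p-value from
#' `t = r * sqrt(T - 2) / sqrt(1 - r^2)` on `T - 2` degrees of freedom.
#' Constant voxel series get `r = 0`, `p = 1` and are flagged.
#'
#' @param scan A [subject_scan()].
#' @param regressor Numeric vector, length equal to the scan's time
#'   dimension; must not be constant.
#' @return A list with 3D arrays `r` and `p` and a logical 3D array
#'   `constant` flagging degenerate voxels.
#' @export
activation_statistics <- function(scan, regressor) {
  stopifnot(inherits(scan, "subject_scan"))
  d <- dim(scan$data)
  if (length(regressor) != d[4])
    stop("regressor length (", length(regressor),
         ") does not match scan time dimension (", d[4], ")")
  if (stats::sd(regressor) == 0) stop("regressor is constant")
  X <- scan_matrix(scan)
  cs <- corr_with_regressors(X, matrix(regressor, ncol = 1))
  r <- cs$r[, 1]
  const <- cs$constant
  r[const] <- 0
  p <- r_to_p(r, d[4])
  p[const] <- 1
  list(r = array(r, dim = d[1:3]), p = array(p, dim = d[1:3]),
       constant = array(const, dim = d[1:3]))
}

# Pearson correlation of every row of X (voxels x time) with every column
# of R (time x k); constant rows are flagged (their r is 0/0 -> set 0)
corr_with_regressors <- function(X, R) {
  nt <- ncol(X)
  Xc <- X - rowMeans(X)
  xs <- sqrt(rowSums(Xc^2))
  const <- xs == 0
  xs[const] <- 1
  Rc <- sweep(R, 2, colMeans(R))
  rs <- sqrt(colSums(Rc^2))
  r <- (Xc %*% Rc) / (xs %o% rs)
  r[const, ] <- 0
  r[r > 1] <- 1
  r[r < -1] <- -1
  list(r = r, constant = const)
}

r_to_p <- function(r, nt) {
  r[r > 1] <- 1
  r[r < -1] <- -1
  den <- 1 - r^2
  den[den < .Machine$double.eps] <- .Machine$double.eps
  tt <- r * sqrt(nt - 2) / sqrt(den)
  2 * stats::pt(-abs(tt), df = nt - 2)
}

#' Temporal signal-stability filter
#'
#' Excludes voxels whose temporal SD exceeds `sd_fraction` of their
#' temporal mean (venous / motion artifact heuristic). Voxels with a
#' non-positive mean have no defined ratio and are excluded and flagged.
#'
#' @param scan A [subject_scan()].
#' @param sd_fraction Allowed SD as a fraction of the mean (> 0),
#'   default 0.08.
#' @return Logical 3D array, `TRUE` where the voxel is retained; the
#'   number of non-positive-mean voxels is attached as attribute
#'   `n_nonpositive_mean` (and a warning is emitted when positive).
#' @export
sd_filter <- function(scan, sd_fraction = 0.08) {
  stopifnot(inherits(scan, "subject_scan"))
  if (!is.finite(sd_fraction) || sd_fraction <= 0)
    stop("`sd_fraction` must be > 0")
  d <- dim(scan$data)
  X <- scan_matrix(scan)
  m <- rowMeans(X)
  s <- sqrt(rowSums((X - m)^2) / (d[4] - 1))
  bad_mean <- m <= 0
  keep <- !bad_mean & (s <= sd_fraction * m)
  if (any(bad_mean))
    warning(sum(bad_mean), " voxel(s) with non-positive temporal mean excluded")
  out <- array(keep, dim = d[1:3])
  attr(out, "n_nonpositive_mean") <- sum(bad_mean)
  out
}

neighbor_offsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3)
  if (is.null(keep)) stop("`connectivity` must be one of 6, 18, 26")
  g <- g[keep, ]
  # one of each +/- pair suffices for undirected adjacency
  g[g$dz > 0 | (g$dz == 0 & g$dy > 0) |
      (g$dz == 0 & g$dy == 0 & g$dx > 0), ]
}

# connected components among the voxels with linear indices `idx` on a grid
# of dimension `dims`; returns an integer component label per element of idx
components_of_indices <- function(idx, dims, connectivity = 6) {
  n <- length(idx)
  if (n <= 1) return(rep(1L, n))
  coord <- arrayInd(idx, dims)
  offs <- neighbor_offsets(connectivity)
  pos <- integer(prod(dims))
  pos[idx] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(offs))) {
    nx <- coord[, 1] + offs$dx[k]
    ny <- coord[, 2] + offs$dy[k]
    nz <- coord[, 3] + offs$dz[k]
    ok <- nx >= 1 & nx <= dims[1] & ny >= 1 & ny <= dims[2] &
      nz >= 1 & nz <= dims[3]
    if (!any(ok)) next
    nidx <- nx[ok] + (ny[ok] - 1) * dims[1] + (nz[ok] - 1) * dims[1] * dims[2]
    j <- pos[nidx]
    hit <- which(ok)[j > 0]
    j <- j[j > 0]
    for (e in seq_along(hit)) {
      a <- find(hit[e]); b <- find(j[e])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Connected components of a voxel mask
#'
#' Partitions the `TRUE` voxels of a 3D mask into maximal connected
#' components under a 6-, 18- or 26-neighborhood.
#'
#' @param mask Logical 3D array.
#' @param connectivity 6, 18 or 26 (default 6, faces only).
#' @return A list of integer vectors of linear voxel indices, ordered by
#'   decreasing size; an empty mask gives an empty list.
#' @export
cluster_components <- function(mask, connectivity = 6) {
  if (!is.array(mask) || length(dim(mask)) != 3)
    stop("`mask` must be a logical 3D array")
  idx <- which(mask)
  if (!length(idx)) return(list())
  comp <- components_of_indices(idx, dim(mask), connectivity)
  out <- split(idx, comp)
  names(out) <- NULL
  out[order(-lengths(out))]
}

max_component_size <- function(idx, dims, connectivity) {
  if (length(idx) <= 1) return(length(idx))
  comp <- components_of_indices(idx, dims, connectivity)
  max(tabulate(comp))
}

#' Activation map with cluster-extent FWE correction
#'
#' The full activation-mapping stage: optional smoothing and detrending,
#' voxel-wise task correlation, the voxel p-value threshold and the
#' SD-stability filter, then cluster-extent family-wise-error correction.
#' The null distribution of the maximum cluster size is estimated from
#' `cfg$n_null` surrogate maps in which the regressor is circularly
#' time-shifted by a random offset shared by all voxels (preserving the
#' spatial and temporal autocorrelation of the data); observed clusters
#' are retained only if larger than the `(1 - fwe_alpha)` quantile of the
#' null maxima. Surrogate offsets are drawn from the current RNG stream;
#' seed beforehand for reproducibility.
#'
#' @param scan A [subject_scan()] (raw; smoothing/detrending applied here
#'   according to `cfg`).
#' @param cfg An [analysis_config()].
#' @return An object of class `activation_map`: 3D arrays `r`, `p`,
#'   `active`, `sd_keep`; `clusters` (list of linear-index vectors);
#'   `cluster_table` (size and peak voxel per cluster);
#'   `extent_threshold`; `null_max_sizes`; and the processed scan as
#'   `processed` (used downstream for network correlations).
#' @export
cluster_threshold <- function(scan, cfg = analysis_config()) {
  stopifnot(inherits(scan, "subject_scan"), inherits(cfg, "analysis_config"))
  if (cfg$n_null < 100)
    warning("n_null < 100: cluster-extent null will be poorly resolved")
  proc <- scan
  if (cfg$smooth_fwhm_mm > 0) proc <- smooth_volume(proc, cfg$smooth_fwhm_mm)
  sd_keep <- sd_filter(proc, cfg$sd_fraction)
  if (cfg$detrend) proc <- detrend_scan(proc)
  d <- dim(proc$data)
  nt <- d[4]
  reg <- hrf_regressor(scan$paradigm, cfg$hrf_peak_s, cfg$hrf_sd_s)
  if (stats::sd(reg) == 0) stop("paradigm yields a constant regressor")

  X <- scan_matrix(proc)
  obs <- corr_with_regressors(X, matrix(reg, ncol = 1))
  r <- obs$r[, 1]
  r[obs$constant] <- 0
  p <- r_to_p(r, nt)
  p[obs$constant] <- 1

  base_keep <- as.vector(sd_keep) & !obs$constant
  obs_idx <- which(p <= cfg$p_voxel & base_keep)

  # Null cluster extents are measured on the task-residual series (the
  # regressor projected out per voxel): with a periodic block design a
  # plain circular shift would re-align the surrogate with the task, so the
  # residuals are what carries the noise-only spatial structure. A shared
  # circular shift of the regressor against the residuals (one offset per
  # surrogate, same for all voxels) preserves spatial and temporal
  # autocorrelation of that noise.
  rc <- reg - mean(reg)
  beta_hat <- (X %*% rc) / sum(rc^2)
  Xres <- X - beta_hat %*% rc
  offsets <- sample.int(nt - 1L, cfg$n_null, replace = TRUE)
  R <- vapply(offsets, function(o) reg[((seq_len(nt) - 1 + o) %% nt) + 1],
              numeric(nt))
  null_r <- corr_with_regressors(Xres, R)$r
  # |r| threshold equivalent to the p threshold (monotone t transform)
  tcrit <- stats::qt(1 - cfg$p_voxel / 2, df = nt - 2)
  rcrit <- tcrit / sqrt(nt - 2 + tcrit^2)
  null_max <- integer(cfg$n_null)
  for (k in seq_len(cfg$n_null)) {
    sidx <- which(abs(null_r[, k]) >= rcrit & base_keep)
    null_max[k] <- max_component_size(sidx, d[1:3], cfg$connectivity)
  }
  extent <- stats::quantile(null_max, 1 - cfg$fwe_alpha, type = 1, names = FALSE)

  clusters <- list()
  if (length(obs_idx)) {
    comp <- components_of_indices(obs_idx, d[1:3], cfg$connectivity)
    cl <- split(obs_idx, comp)
    names(cl) <- NULL
    clusters <- cl[lengths(cl) > extent]
    clusters <- clusters[order(-lengths(clusters))]
  }
  active <- array(FALSE, dim = d[1:3])
  for (cl in clusters) active[cl] <- TRUE
  tab <- if (length(clusters)) {
    peak <- vapply(clusters, function(ix) ix[which.max(r[ix])], numeric(1))
    pc <- arrayInd(peak, d[1:3])
    data.frame(cluster_id = seq_along(clusters), size = lengths(clusters),
               peak_x = pc[, 1] - 1L, peak_y = pc[, 2] - 1L,
               peak_z = pc[, 3] - 1L, peak_r = r[peak])
  } else {
    data.frame(cluster_id = integer(), size = integer(), peak_x = integer(),
               peak_y = integer(), peak_z = integer(), peak_r = numeric())
  }
  structure(list(r = array(r, d[1:3]), p = array(p, d[1:3]), active = active,
                 sd_keep = sd_keep, clusters = clusters, cluster_table = tab,
                 extent_threshold = extent, null_max_sizes = null_max,
                 cfg = cfg, processed = proc),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf(
    "<activation_map> %d active voxel(s) in %d cluster(s); extent threshold %d\n",
    sum(x$active), length(x$clusters), as.integer(x$extent_threshold)))
  invisible(x)
}
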