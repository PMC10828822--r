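#' Build the run-specific 2D peptide density grid
#'
#' Estimates a two-dimensional Gaussian-product kernel density over the
#' (m/z, retention time) coordinates of identified uniquely charged peptide
#' features, evaluated on a square grid (default 200 x 200) spanning the
#' data range padded by one bandwidth per axis. Density values are rescaled
#' to sum to 1, zeros are substituted with the minimum positive value, and
#' the square root is taken (in that order) to shrink extreme differences
#' across the plane.
#'
#' @param mz,rt Numeric vectors of feature coordinates (m/z in Th, retention
#'   time in minutes).
#' @param gridsize Number of grid nodes per axis (default 200).
#' @param bandwidth Optional length-2 numeric vector of axis bandwidths (the
#'   normal reference rule is used when `NULL`).
#' @return An object of class `density_grid`: a list with `mz_axis`,
#'   `rt_axis` and a `gridsize x gridsize` matrix `values` (all positive).
#' @export
build_density <- function(mz, rt, gridsize = 200, bandwidth = NULL) {
  keep <- is.finite(mz) & is.finite(rt)
  # duplicate coordinates carry no information and would shrink the
  # data-driven bandwidth; the estimate is built on distinct features
  u <- unique(cbind(mz[keep], rt[keep]))
  mz <- u[, 1]; rt <- u[, 2]
  if (length(mz) < 2)
    stop("need at least 2 distinct (mz, rt) features for density estimation")
  h <- bandwidth
  if (is.null(h))
    h <- c(MASS::bandwidth.nrd(mz), MASS::bandwidth.nrd(rt))
  if (any(!is.finite(h)) || any(h <= 0))
    stop("degenerate bandwidth: features have zero spread on at least one axis")
  lims <- c(range(mz) + c(-1, 1) * h[1], range(rt) + c(-1, 1) * h[2])
  kd <- MASS::kde2d(mz, rt, h = h, n = gridsize, lims = lims)
  v <- kd$z
  v <- v / sum(v)
  if (any(v == 0)) v[v == 0] <- min(v[v > 0])
  v <- sqrt(v)
  structure(list(mz_axis = kd$x, rt_axis = kd$y, values = v,
                 bandwidth = h), class = "density_grid")
}

#' Bilinear interpolation of a density grid
#'
#' Interpolates grid values at arbitrary (m/z, retention time) coordinates;
#' coordinates outside the grid are clamped to the border.
#'
#' @param grid A `density_grid` from [build_density()].
#' @param mz,rt Numeric query coordinates (vectorized).
#' @return Numeric vector of interpolated density values.
#' @export
interpolate_density <- function(grid, mz, rt) {
  xa <- grid$mz_axis; ya <- grid$rt_axis; v <- grid$values
  nx <- length(xa); ny <- length(ya)
  x <- pmin(pmax(mz, xa[1]), xa[nx])
  y <- pmin(pmax(rt, ya[1]), ya[ny])
  ix <- pmin(pmax(findInterval(x, xa), 1L), nx - 1L)
  iy <- pmin(pmax(findInterval(y, ya), 1L), ny - 1L)
  fx <- (x - xa[ix]) / (xa[ix + 1L] - xa[ix])
  fy <- (y - ya[iy]) / (ya[iy + 1L] - ya[iy])
  v[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
    v[cbind(ix + 1L, iy)] * fx * (1 - fy) +
    v[cbind(ix, iy + 1L)] * (1 - fx) * fy +
    v[cbind(ix + 1L, iy + 1L)] * fx * fy
}

#' Per-PSM noise estimate
#'
#' The proxy for sub-threshold (noise-hidden) interfering ion signal: the
#' average reported noise value of peaks in the preceding MS1 scan's
#' isolation window multiplied by the interpolated run-specific peptide
#' density at the PSM's precursor m/z and MS2 retention time.
#'
#' @param window_noise_mean Numeric vector of average window noise values
#'   (the `window_noise_mean` column of [compute_metrics()]).
#' @param grid A `density_grid` for the PSM's run.
#' @param mz,rt Precursor m/z and MS2 retention time coordinates.
#' @return Numeric vector of noise estimates (signal units).
#' @export
compute_noise_estimate <- function(window_noise_mean, grid, mz, rt) {
  window_noise_mean * interpolate_density(grid, mz, rt)
}

#' Uniquely charged peptide features of a PSM table
#'
#' Distinct (sequence, modifications, charge) triples, each represented by
#' the (precursor m/z, retention time) coordinate of its PSM with maximal
#' total reporter intensity.
#'
#' @param psms PSM data frame.
#' @return Data frame with columns `mz`, `rt` (one row per unique feature).
#' @export
unique_peptide_features <- function(psms) {
  key <- paste(psms$sequence, psms$modifications, psms$charge, sep = "\r")
  total <- rowSums(reporter_matrix(psms), na.rm = TRUE)
  o <- order(key, -total)
  first <- o[!duplicated(key[o])]
  data.frame(mz = psms$precursor_mz[first], rt = psms$retention_time_min[first])
}

#' Append per-PSM noise estimates to a metrics table
#'
#' Builds one density grid per raw file from the table's uniquely charged
#' peptide features and appends a `noise_estimate` column.
#'
#' @param metrics PSM data frame with a `window_noise_mean` column (see
#'   [compute_metrics()]).
#' @param gridsize Grid nodes per axis (default 200).
#' @return List with elements `metrics` (the table with `noise_estimate`
#'   appended) and `grids` (named list of `density_grid` per raw file).
#' @export
add_noise_estimates <- function(metrics, gridsize = 200) {
  grids <- list()
  ne <- rep(NA_real_, nrow(metrics))
  for (rf in unique(metrics$raw_file)) {
    sel <- metrics$raw_file == rf
    feats <- unique_peptide_features(metrics[sel, , drop = FALSE])
    grid <- build_density(feats$mz, feats$rt, gridsize = gridsize)
    grids[[rf]] <- grid
    ne[sel] <- compute_noise_estimate(metrics$window_noise_mean[sel], grid,
                                      metrics$precursor_mz[sel],
                                      metrics$retention_time_min[sel])
  }
  metrics$noise_estimate <- ne
  list(metrics = metrics, grids = grids)
}
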