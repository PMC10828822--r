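#' Between-sample normalization of reporter intensities
#'
#' Median-ratio size factors computed on log2 intensities: each channel's
#' factor is the median, over PSMs quantified in every usable channel, of
#' the difference between the channel's log2 intensity and the PSM's mean
#' log2 intensity. Factors are applied on the log2 scale and the result is
#' back-transformed to the linear scale. Non-positive input values are
#' treated as unusable for factor estimation but are carried through the
#' normalization unchanged in ratio (divided by the channel factor).
#' Channels with fewer than `min_shared` usable shared PSMs get a missing
#' factor and are returned un-normalized, with a warning.
#'
#' @param mat Numeric matrix (PSM x channel) of reporter intensities,
#'   missing values allowed.
#' @param min_shared Minimum shared quantified PSMs per channel (default 10).
#' @return List with `normalized` (linear-scale matrix), `factors`
#'   (linear-scale per-channel divisors) and `log2_factors`.
#' @export
normalize_between_samples <- function(mat, min_shared = 10) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 channels to normalize")
  l <- log2(mat)
  l[!is.finite(l)] <- NA
  usable <- colSums(!is.na(l)) >= min_shared
  if (!any(usable)) stop("no channel has enough quantified PSMs")
  complete <- rowSums(is.na(l[, usable, drop = FALSE])) == 0
  if (sum(complete) < min_shared)
    stop("fewer than ", min_shared, " PSMs shared across usable channels")
  ref <- rowMeans(l[complete, usable, drop = FALSE])
  log2_factors <- rep(NA_real_, ncol(mat))
  names(log2_factors) <- colnames(mat)
  for (j in which(usable))
    log2_factors[j] <- stats::median(l[complete, j] - ref)
  partially_usable <- !usable & colSums(!is.na(l)) > 0
  if (any(partially_usable)) {
    warning("channel(s) without enough shared PSMs left un-normalized: ",
            paste(colnames(mat)[partially_usable], collapse = ", "))
  }
  factors <- 2^log2_factors
  div <- ifelse(is.na(factors), 1, factors)
  normalized <- sweep(mat, 2, div, `/`)
  list(normalized = normalized, factors = factors,
       log2_factors = log2_factors)
}

#' PSM-wise interference correction of reporter intensities
#'
#' Subtracts the estimated interference background from each channel:
#' `I_c_corrected = I_c - Ibar * min(EIL, cap)`, where `Ibar` is the mean of
#' the PSM's normalized intensities over the non-empty peptide channels
#' (missing values and empty channels excluded) and the EIL is capped
#' (default 0.8) to mitigate overcorrection. Corrected values that fall
#' below the spectrum-wise minimum peak intensity are replaced with that
#' minimum, and missing reporter values are substituted with it equally.
#' PSMs with undefined `Ibar` or missing EIL are skipped (returned
#' unchanged).
#'
#' Applying the correction twice over-corrects; the operation is not
#' idempotent.
#'
#' @param norm_mat Numeric matrix (PSM x channel) of between-sample
#'   normalized, linear-scale reporter intensities.
#' @param eil Numeric vector of per-PSM estimated interference levels.
#' @param layout A [channel_layout()]; correction is restricted to its
#'   non-empty peptide channels.
#' @param cap EIL ceiling (default 0.8).
#' @param spectrum_min Optional numeric vector of per-PSM minimum observed
#'   MS2 peak intensities; defaults to the per-PSM minimum non-missing
#'   normalized reporter intensity.
#' @return List with `corrected` (matrix) and `skipped` (logical vector of
#'   PSMs left unchanged).
#' @export
correct_interference <- function(norm_mat, eil, layout, cap = 0.8,
                                 spectrum_min = NULL) {
  norm_mat <- as.matrix(norm_mat)
  stopifnot(length(eil) == nrow(norm_mat))
  ch <- intersect(peptide_channels(layout), colnames(norm_mat))
  if (!length(ch)) stop("no peptide channels present in the matrix")
  sub <- norm_mat[, ch, drop = FALSE]
  ibar <- rowMeans(sub, na.rm = TRUE)
  if (is.null(spectrum_min)) {
    spectrum_min <- apply(sub, 1, function(r)
      if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
  }
  skipped <- !is.finite(ibar) | is.na(eil)
  corrected <- norm_mat
  act <- which(!skipped)
  if (length(act)) {
    adj <- ibar[act] * pmin(eil[act], cap)
    newsub <- sub[act, , drop = FALSE] - adj
    floor_m <- matrix(spectrum_min[act], nrow = length(act), ncol = length(ch))
    newsub <- pmax(newsub, floor_m)
    newsub[is.na(sub[act, , drop = FALSE])] <-
      floor_m[is.na(sub[act, , drop = FALSE])]
    corrected[act, ch] <- newsub
  }
  list(corrected = corrected, skipped = skipped)
}
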