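#' Aggregate PSM-level quantities to protein or PTM-site features
#'
#' Channel intensities are combined by summation over each feature's PSMs
#' (missing values excluded; a channel with no quantified PSM stays
#' missing), and PSM estimated interference levels are combined into one
#' intensity-weighted average per feature, with weights equal to each PSM's
#' total reporter intensity. Features quantified via interference-free
#' acquisition (e.g. FAIMS-MS3) get an EIL of 0.
#'
#' @param intensities Numeric matrix (PSM x channel) of normalized
#'   intensities.
#' @param eil Numeric vector of per-PSM EILs.
#' @param feature_id Character/factor vector mapping each PSM to a feature
#'   (protein group or PTM site).
#' @param ms3 Optional logical vector (per PSM); features whose PSMs are
#'   all MS3-quantified get EIL 0.
#' @return List with `intensities` (feature x channel matrix), `eil`
#'   (named vector; missing for features with zero total intensity) and
#'   `n_psms`.
#' @export
aggregate_features <- function(intensities, eil, feature_id, ms3 = NULL) {
  intensities <- as.matrix(intensities)
  stopifnot(nrow(intensities) == length(eil),
            nrow(intensities) == length(feature_id))
  f <- factor(feature_id)
  zeroed <- ifelse(is.na(intensities), 0, intensities)
  sums <- rowsum(zeroed, f)
  counts <- rowsum((!is.na(intensities)) * 1L, f)
  sums[counts == 0] <- NA
  w <- rowSums(intensities, na.rm = TRUE)
  wt <- ifelse(is.na(eil), 0, w)
  agg_eil <- as.numeric(rowsum(wt * ifelse(is.na(eil), 0, eil), f)) /
    as.numeric(rowsum(wt, f))
  agg_eil[!is.finite(agg_eil)] <- NA_real_
  names(agg_eil) <- levels(f)
  if (!is.null(ms3)) {
    all_ms3 <- tapply(ms3, f, all)
    agg_eil[names(all_ms3)[which(all_ms3)]] <- 0
  }
  list(intensities = sums, eil = agg_eil,
       n_psms = as.integer(table(f)))
}

#' Interference-balanced site-to-protein ratio
#'
#' Before dividing a PTM site's channel intensities by its parent protein's,
#' the feature with the lower estimated interference level is adjusted by
#' adding a uniform interference background until the two levels are equal:
#' with `dEIL = EIL_site - EIL_protein > 0` the protein intensities receive
#' `dInterference = Ibar_p * (1 - EIL_p) / (1 - EIL_s) - Ibar_p` in every
#' channel (`Ibar_p` being the protein's mean intensity over the non-empty
#' channels); with `dEIL < 0` the site is adjusted symmetrically; with
#' `dEIL = 0` no adjustment is made. Channel-wise ratios are then divided
#' by their median so the normalized ratios have median 1.
#'
#' @param site_int,protein_int Named numeric channel vectors of aggregated
#'   normalized intensities (missing allowed; missing in either partner
#'   propagates to a missing ratio).
#' @param site_eil,protein_eil Aggregated EILs of the pair.
#' @param layout A [channel_layout()]; `Ibar` averages over its non-empty
#'   channels.
#' @return List with `ratio`, `ratio_norm`, `delta_eil`,
#'   `delta_interference` and `adjusted` (`"site"`, `"protein"` or
#'   `"none"`); `NULL` when the lower-interference feature has EIL 1 (the
#'   adjustment is undefined) or no channel is shared.
#' @export
balance_and_ratio <- function(site_int, site_eil, protein_int, protein_eil,
                              layout) {
  ch <- intersect(peptide_channels(layout),
                  intersect(names(site_int), names(protein_int)))
  if (!length(ch)) return(NULL)
  s <- site_int[ch]; p <- protein_int[ch]
  if (all(is.na(s) | is.na(p))) return(NULL)
  delta_eil <- site_eil - protein_eil
  delta_interference <- 0
  adjusted <- "none"
  if (is.na(delta_eil)) return(NULL)
  if (delta_eil > 0) {
    if (site_eil >= 1) return(NULL)
    ibar <- mean(p, na.rm = TRUE)
    delta_interference <- ibar * (1 - protein_eil) / (1 - site_eil) - ibar
    p <- p + delta_interference
    adjusted <- "protein"
  } else if (delta_eil < 0) {
    if (protein_eil >= 1) return(NULL)
    ibar <- mean(s, na.rm = TRUE)
    delta_interference <- ibar * (1 - site_eil) / (1 - protein_eil) - ibar
    s <- s + delta_interference
    adjusted <- "site"
  }
  ratio <- s / p
  med <- stats::median(ratio, na.rm = TRUE)
  if (!is.finite(med) || med <= 0) return(NULL)
  list(ratio = ratio, ratio_norm = ratio / med, delta_eil = delta_eil,
       delta_interference = delta_interference, adjusted = adjusted)
}

#' Site-to-protein normalization over a mapping table
#'
#' Applies [balance_and_ratio()] to every site/protein pair of a mapping.
#' Sites mapping to several protein groups are normalized against the group
#' with the most quantified PSMs (ties broken alphabetically).
#'
#' @param sites,proteins Aggregates from [aggregate_features()].
#' @param mapping Data frame with columns `site_id`, `protein_id`.
#' @param layout A [channel_layout()].
#' @return Data frame with one row per (site, channel) pair: `site_id`,
#'   `protein_id`, `channel`, `ratio`, `ratio_norm`, `delta_eil`.
#' @export
normalize_sites <- function(sites, proteins, mapping, layout) {
  stopifnot(all(c("site_id", "protein_id") %in% names(mapping)))
  np <- stats::setNames(proteins$n_psms, rownames(proteins$intensities))
  pick <- function(pids) {
    pids <- pids[pids %in% rownames(proteins$intensities)]
    if (!length(pids)) return(NA_character_)
    pids[order(-np[pids], pids)][1]
  }
  out <- list()
  for (sid in unique(mapping$site_id)) {
    if (!sid %in% rownames(sites$intensities)) next
    pid <- pick(mapping$protein_id[mapping$site_id == sid])
    if (is.na(pid)) next
    res <- balance_and_ratio(sites$intensities[sid, ], sites$eil[[sid]],
                             proteins$intensities[pid, ], proteins$eil[[pid]],
                             layout)
    if (is.null(res)) next
    out[[length(out) + 1L]] <- data.frame(
      site_id = sid, protein_id = pid, channel = names(res$ratio),
      ratio = as.numeric(res$ratio), ratio_norm = as.numeric(res$ratio_norm),
      delta_eil = res$delta_eil, row.names = NULL)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
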