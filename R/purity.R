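NEUTRON_MASS <- 1.00335484

#' Extract the isolation-window content of the MS1 scans bordering a PSM
#'
#' Collects all centroided peaks inside the PSM's isolation window (the
#' closed interval `precursor_mz +/- isolation_width/2`, assuming uniform
#' isolation efficiency) from the two MS1 scans bordering the MS2 scan,
#' flags precursor-derived peaks, and computes retention-time weights.
#'
#' The branch logic is:
#' \enumerate{
#'   \item The precursor peak is searched in the preceding MS1 scan within
#'     +/- `precursor_tol` Th of the declared precursor m/z. If absent, the
#'     second-last MS1 scan substitutes as the preceding scan, provided the
#'     precursor is found there. If still absent, the precursor intensity is
#'     imputed at the declared m/z as the minimum peak intensity over all
#'     peaks of the preceding scan.
#'   \item The following MS1 scan is skipped if its isolation window is
#'     empty. If it is non-empty but lacks the precursor peak, the precursor
#'     is imputed as above - except when the precursor was found in neither
#'     bordering scan, in which case the following scan is skipped.
#'   \item Heavy (+1) and light (-1) isotope peaks of the precursor are
#'     flagged as precursor-derived using an m/z spacing of
#'     `1.00335484 / charge` and a tolerance of +/- `isotope_tol` Th.
#'   \item Peak intensities are weighted by `w_i = 1 - d_i / sum(d_i)` where
#'     `d_i` is the absolute retention-time difference between MS1 scan `i`
#'     and the MS2 scan; a single usable scan receives weight 1.
#' }
#'
#' @param psm One-row data frame (or list) with fields `ms2_scan`,
#'   `precursor_mz`, `retention_time_min`, `charge`, `isolation_width`.
#' @param run An `ms1_run` object for the PSM's raw file (see
#'   [as_ms1_runs()]).
#' @param precursor_tol Precursor matching tolerance in Th (default 0.0025).
#' @param isotope_tol Isotope matching tolerance in Th (default 0.00125).
#' @return An object of class `isolation_window_extract`: a list with
#'   elements `ok`, `flag`, per-peak vectors `wint` (weighted intensity),
#'   `is_precursor`, `side`, per-scan `scans` metadata (side, scan number,
#'   `d`, `w`, peak count), `imputed`, and `window_noise` (noise values of
#'   the real peaks in the preceding scan's window, falling back to the
#'   nearest peak in m/z when the window is empty).
#' @export
extract_isolation_window <- function(psm, run, precursor_tol = 0.0025,
                                     isotope_tol = 0.00125) {
  pm <- psm$precursor_mz
  half <- psm$isolation_width / 2
  t_ms2 <- psm$retention_time_min
  charge <- max(1L, as.integer(psm$charge))
  fail <- function(flag) structure(list(ok = FALSE, flag = flag),
                                   class = "isolation_window_extract")

  n_prev <- findInterval(psm$ms2_scan - 0.5, run$scan_numbers)
  if (n_prev < 1) return(fail("no_preceding_ms1_scan"))
  idx_fol <- if (n_prev < length(run$scan_numbers)) n_prev + 1L else NA_integer_

  window_peaks <- function(idx) {
    p <- run$peaks[[idx]]
    p[p$mz >= pm - half & p$mz <= pm + half, , drop = FALSE]
  }
  find_prec <- function(p) which(abs(p$mz - pm) <= precursor_tol)

  # preceding scan, with second-last substitution
  idx_prev <- n_prev
  wp_prev <- window_peaks(idx_prev)
  prec_prev <- find_prec(wp_prev)
  substituted <- FALSE
  if (!length(prec_prev) && n_prev >= 2) {
    wp_second <- window_peaks(n_prev - 1L)
    if (length(find_prec(wp_second))) {
      idx_prev <- n_prev - 1L
      wp_prev <- wp_second
      prec_prev <- find_prec(wp_prev)
      substituted <- TRUE
    }
  }
  prec_found_prev <- length(prec_prev) > 0
  imputed_prev <- FALSE
  impute_value <- NA_real_
  if (!prec_found_prev) {
    all_prev <- run$peaks[[idx_prev]]
    if (nrow(all_prev) == 0) return(fail("preceding_scan_empty"))
    impute_value <- min(all_prev$intensity)
    wp_prev <- rbind(wp_prev,
                     data.frame(mz = pm, intensity = impute_value,
                                noise = NA_real_))
    wp_prev <- wp_prev[order(wp_prev$mz), , drop = FALSE]
    imputed_prev <- TRUE
  } else {
    all_prev <- run$peaks[[idx_prev]]
    impute_value <- min(all_prev$intensity)
  }

  # following scan
  use_fol <- FALSE
  imputed_fol <- FALSE
  wp_fol <- NULL
  if (!is.na(idx_fol)) {
    wp_fol <- window_peaks(idx_fol)
    if (nrow(wp_fol) > 0) {
      if (length(find_prec(wp_fol))) {
        use_fol <- TRUE
      } else if (prec_found_prev) {
        wp_fol <- rbind(wp_fol,
                        data.frame(mz = pm, intensity = impute_value,
                                   noise = NA_real_))
        wp_fol <- wp_fol[order(wp_fol$mz), , drop = FALSE]
        use_fol <- TRUE
        imputed_fol <- TRUE
      }  # precursor found nowhere: following scan is skipped
    }
  }

  flag_precursor <- function(p) {
    iso <- NEUTRON_MASS / charge
    abs(p$mz - pm) <= precursor_tol |
      abs(p$mz - (pm + iso)) <= isotope_tol |
      abs(p$mz - (pm - iso)) <= isotope_tol
  }

  sides <- list(list(side = -1L, idx = idx_prev, peaks = wp_prev,
                     imputed = imputed_prev))
  if (use_fol)
    sides <- c(sides, list(list(side = 1L, idx = idx_fol, peaks = wp_fol,
                                imputed = imputed_fol)))
  d <- vapply(sides, function(s)
    abs(run$retention_times[s$idx] - t_ms2), numeric(1))
  w <- if (length(d) == 1) 1 else 1 - d / sum(d)

  wint <- numeric(0); is_prec <- logical(0); side_vec <- integer(0)
  scans <- list()
  for (k in seq_along(sides)) {
    s <- sides[[k]]
    fp <- flag_precursor(s$peaks)
    wint <- c(wint, w[k] * s$peaks$intensity)
    is_prec <- c(is_prec, fp)
    side_vec <- c(side_vec, rep(s$side, nrow(s$peaks)))
    scans[[k]] <- list(side = s$side, scan_number = run$scan_numbers[s$idx],
                       retention_time = run$retention_times[s$idx],
                       d = d[k], w = w[k], n_peaks = nrow(s$peaks),
                       imputed = s$imputed)
  }

  # noise values of real (non-imputed) peaks in the preceding scan's window;
  # empty window falls back to the nearest peak in m/z within that scan
  real_prev <- wp_prev[!is.na(wp_prev$noise), , drop = FALSE]
  if (nrow(real_prev) > 0) {
    window_noise <- real_prev$noise
  } else {
    all_prev <- run$peaks[[idx_prev]]
    window_noise <- if (nrow(all_prev))
      all_prev$noise[which.min(abs(all_prev$mz - pm))] else NA_real_
  }

  structure(list(ok = TRUE, flag = if (substituted) "second_last_substituted" else "ok",
                 wint = wint, is_precursor = is_prec, side = side_vec,
                 scans = scans, imputed = imputed_prev || imputed_fol,
                 window_noise = window_noise),
            class = "isolation_window_extract")
}

#' Precursor purity fraction of an isolation-window extract
#'
#' The fraction of retention-time-weighted isolation-window signal that is
#' attributable to the precursor peptide (including its +/-1 isotopes).
#'
#' @param extract An `isolation_window_extract` from
#'   [extract_isolation_window()].
#' @return A fraction in `[0, 1]`, or `NA` when the extract failed or the
#'   total weighted intensity is zero.
#' @export
compute_ppf <- function(extract) {
  if (!isTRUE(extract$ok)) return(NA_real_)
  tot <- sum(extract$wint)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  sum(extract$wint[extract$is_precursor]) / tot
}

#' Total weighted intensity in the isolation window
#'
#' The denominator of the precursor purity fraction: the sum of all
#' retention-time-weighted peak intensities in the isolation window of the
#' used bordering MS1 scans.
#'
#' @inheritParams compute_ppf
#' @return Total weighted intensity (signal units), or `NA` on failure.
#' @export
compute_tiw <- function(extract) {
  if (!isTRUE(extract$ok)) return(NA_real_)
  sum(extract$wint)
}

#' Total peptide ion current of MS2 scans
#'
#' The MS2 total ion current minus the summed reporter ion intensity of the
#' same scan (missing reporters treated as 0); negative differences are
#' clamped to 0 with a warning.
#'
#' @param tic Numeric vector of MS2 total ion currents.
#' @param reporters Numeric matrix (PSM x channel) of reporter intensities,
#'   or a numeric vector for a single PSM.
#' @return Numeric vector of PIC values.
#' @export
compute_pic <- function(tic, reporters) {
  if (is.null(dim(reporters))) reporters <- matrix(reporters, nrow = 1)
  rs <- rowSums(reporters, na.rm = TRUE)
  pic <- tic - rs
  if (any(pic < 0, na.rm = TRUE)) {
    warning(sum(pic < 0, na.rm = TRUE),
            " PSM(s) with reporter sum exceeding TIC; PIC clamped to 0")
    pic <- pmax(pic, 0)
  }
  pic
}

#' Observed interference level of a PSM (ground-truth designs)
#'
#' For spike-in designs with channels known to be free of the spiked
#' proteome, the OIL is the ratio of the average normalized reporter
#' intensity over the interference-only channels to the average over the
#' remaining peptide channels, capped at 1. Missing values are excluded from
#' each average. Intensities must be between-sample normalized and
#' back-transformed to the linear scale.
#'
#' @param intensities Named numeric vector (or PSM x channel matrix) of
#'   normalized reporter intensities.
#' @param layout A [channel_layout()] declaring interference-only channels.
#' @return OIL fraction(s) in `[0, 1]`; `NA` where the denominator average
#'   is zero or undefined.
#' @export
compute_oil <- function(intensities, layout) {
  if (!length(layout$interference_only_channels))
    stop("layout declares no interference-only channels")
  if (is.null(dim(intensities)))
    intensities <- matrix(intensities, nrow = 1,
                          dimnames = list(NULL, names(intensities)))
  num_ch <- intersect(layout$interference_only_channels, colnames(intensities))
  den_ch <- intersect(oil_denominator_channels(layout), colnames(intensities))
  num <- rowMeans(intensities[, num_ch, drop = FALSE], na.rm = TRUE)
  den <- rowMeans(intensities[, den_ch, drop = FALSE], na.rm = TRUE)
  oil <- ifelse(!is.finite(den) | den <= 0, NA_real_, pmin(num / den, 1))
  ifelse(is.finite(oil) | is.na(oil), oil, NA_real_)
}

#' Compute PSM-wise purity and signal metrics
#'
#' Appends the per-PSM metrics `ppf`, `tiw`, `pic`, `window_noise_mean`
#' (average noise value of the preceding-scan isolation-window peaks, the
#' first factor of the noise estimate) and a `metric_flag` column to a PSM
#' table. When the layout declares interference-only channels, an `oil`
#' column is added, computed from between-sample-normalized intensities.
#'
#' @param psms PSM data frame (see [read_psm_table()]).
#' @param ms1_runs Named list of `ms1_run` objects (see
#'   [read_ms1_snapshots()]).
#' @param layout A [channel_layout()].
#' @param precursor_tol,isotope_tol Matching tolerances in Th.
#' @param oil Logical; compute OIL when the layout supports it.
#' @return The PSM data frame with metric columns appended.
#' @export
compute_metrics <- function(psms, ms1_runs, layout,
                            precursor_tol = 0.0025, isotope_tol = 0.00125,
                            oil = TRUE) {
  n <- nrow(psms)
  ppf <- tiw <- noise_mean <- rep(NA_real_, n)
  flag <- rep("ok", n)
  for (i in seq_len(n)) {
    run <- ms1_runs[[psms$raw_file[i]]]
    if (is.null(run)) { flag[i] <- "no_ms1_data"; next }
    ex <- extract_isolation_window(psms[i, ], run,
                                   precursor_tol = precursor_tol,
                                   isotope_tol = isotope_tol)
    if (!isTRUE(ex$ok)) { flag[i] <- ex$flag; next }
    ppf[i] <- compute_ppf(ex)
    tiw[i] <- compute_tiw(ex)
    noise_mean[i] <- mean(ex$window_noise)
    if (is.na(ppf[i]) && ex$flag == "ok") flag[i] <- "zero_window_intensity"
    else if (ex$flag != "ok") flag[i] <- ex$flag
  }
  rep_mat <- reporter_matrix(psms, layout)
  psms$ppf <- ppf
  psms$tiw <- tiw
  psms$pic <- compute_pic(psms$tic, rep_mat)
  psms$window_noise_mean <- noise_mean
  psms$metric_flag <- flag
  if (oil && length(layout$interference_only_channels)) {
    norm <- normalize_between_samples(rep_mat)
    psms$oil <- as.numeric(compute_oil(norm$normalized, layout))
  }
  psms
}
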