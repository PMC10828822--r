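#' Read a PSM table
#'
#' Ingests a tab-separated PSM (peptide-spectrum match) table in a
#' MaxQuant-evidence-like dialect: one row per PSM, header-keyed columns
#' `raw_file`, `ms2_scan`, `sequence`, `modifications`, `charge`,
#' `precursor_mz`, `retention_time_min`, `tic` plus one `reporter_<channel>`
#' column per quantified channel. Optional columns (`isolation_width`,
#' `species_tag`, `protein_id`, `compensation_voltage`, `ms3_quantified`,
#' `psm_id`) are carried through when present. Reporter cells that cannot be
#' parsed as numbers become missing values (never zero); an explicit `0` in
#' the input is kept as 0.
#'
#' @param path TSV file path.
#' @param layout A [channel_layout()]; reporter columns must refer to layout
#'   channels.
#' @param default_isolation_width Isolation window width (Th) used when the
#'   table has no `isolation_width` column.
#' @return A data frame with one row per PSM.
#' @export
read_psm_table <- function(path, layout, default_isolation_width = 0.7) {
  if (!file.exists(path)) stop("PSM table not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("raw_file", "ms2_scan", "sequence", "modifications",
                "charge", "precursor_mz", "retention_time_min", "tic")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("PSM table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  rep_cols <- grep("^reporter_", names(d), value = TRUE)
  rep_channels <- sub("^reporter_", "", rep_cols)
  unknown <- setdiff(rep_channels, layout$channel_names)
  if (length(unknown))
    stop("reporter columns refer to channels absent from the layout: ",
         paste(unknown, collapse = ", "))
  num_cols <- c("ms2_scan", "charge", "precursor_mz", "retention_time_min",
                "tic", rep_cols,
                intersect(c("isolation_width", "compensation_voltage"), names(d)))
  for (cc in num_cols)
    d[[cc]] <- suppressWarnings(as.numeric(d[[cc]]))
  d$ms2_scan <- as.integer(d$ms2_scan)
  d$charge <- as.integer(d$charge)
  if (!"isolation_width" %in% names(d))
    d$isolation_width <- default_isolation_width
  if ("ms3_quantified" %in% names(d))
    d$ms3_quantified <- as.logical(d$ms3_quantified)
  if (!"psm_id" %in% names(d))
    d$psm_id <- paste(d$raw_file, d$ms2_scan, sep = ":")
  if (any(d$charge < 1, na.rm = TRUE))
    stop("charge must be >= 1 for every PSM")
  d
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]. Numeric fields are serialized with 17
#' significant digits so that a read/write round trip reproduces doubles
#' bit-identically.
#'
#' @param psms PSM data frame.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_psm_table <- function(psms, path) {
  out <- psms
  for (cc in names(out)) {
    if (is.double(out[[cc]]))
      out[[cc]] <- ifelse(is.na(out[[cc]]), "",
                          formatC(out[[cc]], digits = 17, format = "g"))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read MS1 spectral snapshots
#'
#' Reads a long-format TSV of centroided MS1 peaks (columns `raw_file`,
#' `scan_number`, `retention_time_min`, `mz`, `intensity`, `noise`) and
#' assembles, per raw file, the ordered sequence of MS1 scan snapshots the
#' purity metrics operate on. Rows with non-positive noise values are
#' rejected with a warning reporting the count. Scans with no surviving
#' peaks are retained as empty snapshots.
#'
#' @param path TSV file path.
#' @return Named list (by raw file) of `ms1_run` objects; see
#'   [as_ms1_runs()] for the structure.
#' @export
read_ms1_snapshots <- function(path) {
  if (!file.exists(path)) stop("MS1 snapshot table not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("raw_file", "scan_number", "retention_time_min",
                "mz", "intensity", "noise")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("MS1 snapshot table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  as_ms1_runs(d)
}

#' Assemble MS1 snapshot runs from a long-format data frame
#'
#' @param d Data frame with columns `raw_file`, `scan_number`,
#'   `retention_time_min`, `mz`, `intensity`, `noise`. A peak with `mz` set
#'   to `NA` encodes an intentionally empty scan (the scan is kept with an
#'   empty peak list).
#' @return Named list of `ms1_run` objects, each a list with sorted
#'   `scan_numbers`, matching `retention_times` and `peaks` (a list of
#'   data frames with columns `mz`, `intensity`, `noise`, sorted by `mz`).
#' @export
as_ms1_runs <- function(d) {
  has_peak <- !is.na(d$mz)
  bad <- has_peak & (is.na(d$noise) | d$noise <= 0)
  if (any(bad)) {
    warning(sum(bad), " MS1 peak row(s) with non-positive noise rejected")
    d <- d[!bad, , drop = FALSE]
    has_peak <- !is.na(d$mz)
  }
  runs <- list()
  for (rf in unique(d$raw_file)) {
    dr <- d[d$raw_file == rf, , drop = FALSE]
    key <- paste(dr$scan_number)
    scans <- !duplicated(dr$scan_number)
    scan_numbers <- dr$scan_number[scans]
    rts <- dr$retention_time_min[scans]
    o <- order(scan_numbers)
    scan_numbers <- scan_numbers[o]
    rts <- rts[o]
    peaks <- vector("list", length(scan_numbers))
    idx <- split(seq_len(nrow(dr)), factor(dr$scan_number, levels = scan_numbers))
    for (k in seq_along(scan_numbers)) {
      rows <- idx[[k]]
      rows <- rows[!is.na(dr$mz[rows])]
      p <- data.frame(mz = dr$mz[rows], intensity = dr$intensity[rows],
                      noise = dr$noise[rows])
      p <- p[order(p$mz), , drop = FALSE]
      rownames(p) <- NULL
      peaks[[k]] <- p
    }
    runs[[rf]] <- structure(list(raw_file = rf, scan_numbers = scan_numbers,
                                 retention_times = rts, peaks = peaks),
                            class = "ms1_run")
  }
  runs
}

#' Write MS1 snapshot runs to a long-format TSV
#'
#' @param runs Named list of `ms1_run` objects (or a long-format data frame,
#'   written as is).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_ms1_snapshots <- function(runs, path) {
  if (is.data.frame(runs)) {
    d <- runs
  } else {
    rows <- list()
    for (run in runs) {
      for (k in seq_along(run$scan_numbers)) {
        p <- run$peaks[[k]]
        if (nrow(p) == 0)
          p <- data.frame(mz = NA_real_, intensity = NA_real_, noise = NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          raw_file = run$raw_file, scan_number = run$scan_numbers[k],
          retention_time_min = run$retention_times[k],
          mz = p$mz, intensity = p$intensity, noise = p$noise)
      }
    }
    d <- do.call(rbind, rows)
  }
  for (cc in c("retention_time_min", "mz", "intensity", "noise"))
    if (cc %in% names(d) && is.double(d[[cc]]))
      d[[cc]] <- ifelse(is.na(d[[cc]]), "",
                        formatC(d[[cc]], digits = 17, format = "g"))
  utils::write.table(d, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Infer reporter ion intensities from an MS2 peak list
#'
#' For each layout channel, takes the maximum observed peak intensity within
#' a closed +/- `tol` Th window around the expected reporter m/z. Channels
#' with no peak in the window are missing (`NA`), not zero.
#'
#' @param ms2_peaks Data frame (or 2-column matrix) with columns `mz` and
#'   `intensity`.
#' @param layout A [channel_layout()].
#' @param tol Half-width of the matching window in Th (default 0.002).
#' @return Named numeric vector, one element per layout channel.
#' @export
infer_reporter_intensities <- function(ms2_peaks, layout, tol = 0.002) {
  if (tol <= 0) stop("tol must be positive")
  rmz <- sort(layout$reporter_mz)
  if (length(rmz) > 1 && any(diff(rmz) <= 2 * tol))
    stop("reporter windows overlap at tol = ", tol,
         "; reduce tol or check the layout's reporter m/z values")
  ms2_peaks <- as.data.frame(ms2_peaks)
  out <- stats::setNames(rep(NA_real_, length(layout$channel_names)),
                         layout$channel_names)
  for (ch in layout$channel_names) {
    sel <- abs(ms2_peaks$mz - layout$reporter_mz[[ch]]) <= tol
    if (any(sel)) out[[ch]] <- max(ms2_peaks$intensity[sel])
  }
  out
}

#' Correct reporter intensities for isotopic impurities
#'
#' Solves the linear system `observed = M %*% true` for the true channel
#' intensities, where `M` is the manufacturer impurity matrix (columns =
#' labeled channel, rows = detected channel). Missing intensities are
#' imputed as 0 for the solve and restored to missing afterwards; negative
#' solutions are clamped to 0.
#'
#' @param intensities Named numeric vector of observed channel intensities
#'   (missing allowed).
#' @param impurity_matrix Square numeric matrix, dimension equal to
#'   `length(intensities)`.
#' @return Named numeric vector of corrected intensities.
#' @export
correct_isotopic_impurities <- function(intensities, impurity_matrix) {
  M <- as.matrix(impurity_matrix)
  n <- length(intensities)
  if (nrow(M) != n || ncol(M) != n)
    stop("impurity matrix must be square with dimension = number of channels")
  kap <- kappa(M, exact = FALSE)
  if (!is.finite(kap) || kap > 1e12)
    stop(sprintf("impurity matrix is singular or near-singular (condition number %.3g)", kap))
  miss <- is.na(intensities)
  obs <- ifelse(miss, 0, intensities)
  sol <- solve(M, obs)
  sol <- pmax(sol, 0)
  sol[miss] <- NA_real_
  stats::setNames(as.numeric(sol), names(intensities))
}

#' Extract the reporter intensity matrix from a PSM table
#'
#' @param psms PSM data frame with `reporter_<channel>` columns.
#' @param layout Optional [channel_layout()]; restricts and orders columns
#'   to layout channels.
#' @return Numeric matrix (PSM x channel) with channel names as colnames.
#' @export
reporter_matrix <- function(psms, layout = NULL) {
  rep_cols <- grep("^reporter_", names(psms), value = TRUE)
  channels <- sub("^reporter_", "", rep_cols)
  if (!is.null(layout)) {
    keep <- channels %in% layout$channel_names
    rep_cols <- rep_cols[keep]
    channels <- channels[keep]
    o <- order(match(channels, layout$channel_names))
    rep_cols <- rep_cols[o]
    channels <- channels[o]
  }
  m <- as.matrix(psms[, rep_cols, drop = FALSE])
  colnames(m) <- channels
  rownames(m) <- psms$psm_id
  m
}
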