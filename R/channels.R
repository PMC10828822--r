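#' Channel layout for an isobaric labeling experiment
#'
#' A channel layout bundles everything the quantification pipeline needs to
#' know about the multiplex design: channel names in plex order, expected
#' reporter ion m/z per channel, an optional isotopic impurity matrix,
#' channels known to carry no peptide material (e.g. a label-only blank),
#' channels that carry only background signal (interference-only channels of
#' a spike-in design) and the group design mapping groups of channels to a
#' relative spike abundance.
#'
#' @param channel_names Character vector of channel labels in plex order,
#'   e.g. `c("126C", "127N", ...)`.
#' @param reporter_mz Named numeric vector mapping each channel to its
#'   expected reporter ion m/z (Th).
#' @param impurity_matrix Optional square numeric matrix of isotopic impurity
#'   fractions; columns index the labeled channel, rows the channel in which
#'   signal is detected. Columns must each sum to at most 1 (+1e-9).
#' @param empty_channels Channels carrying no peptide (label-only blanks or
#'   unused plex positions).
#' @param interference_only_channels Channels whose reporter signal stems
#'   exclusively from the uniform background proteome (spike-free channels
#'   of a two-proteome design). Must be disjoint from `empty_channels`.
#' @param groups Named list of design groups, each a
#'   `list(channels = <character>, amount = <numeric>)` giving the channel
#'   subset and the relative spiked-proteome abundance. Every group channel
#'   must appear in exactly one group.
#'
#' @return An object of class `channel_layout`.
#' @seealso [tmtpro16_twoproteome_layout()] for the built-in two-proteome
#'   preset, [design_fold_changes()] for the implied group ratios.
#' @export
channel_layout <- function(channel_names, reporter_mz, impurity_matrix = NULL,
                           empty_channels = character(),
                           interference_only_channels = character(),
                           groups = list()) {
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names))
    stop("duplicated channel names in layout")
  if (!all(channel_names %in% names(reporter_mz)))
    stop("reporter_mz must name every channel")
  reporter_mz <- reporter_mz[channel_names]
  if (!is.null(impurity_matrix)) {
    impurity_matrix <- as.matrix(impurity_matrix)
    if (nrow(impurity_matrix) != length(channel_names) ||
        ncol(impurity_matrix) != length(channel_names))
      stop("impurity_matrix must be square with one row/column per channel")
    if (any(colSums(impurity_matrix) > 1 + 1e-9))
      stop("impurity_matrix columns must each sum to <= 1")
    dimnames(impurity_matrix) <- list(channel_names, channel_names)
  }
  bad <- setdiff(c(empty_channels, interference_only_channels), channel_names)
  if (length(bad))
    stop("unknown channels: ", paste(bad, collapse = ", "))
  if (length(intersect(empty_channels, interference_only_channels)))
    stop("interference-only channels cannot also be empty channels")
  if (length(groups)) {
    gch <- unlist(lapply(groups, `[[`, "channels"), use.names = FALSE)
    if (anyDuplicated(gch))
      stop("each channel may appear in at most one group")
    if (!all(gch %in% channel_names))
      stop("group channels must be layout channels")
    if (any(gch %in% empty_channels))
      stop("empty channels cannot belong to a design group")
    amounts <- vapply(groups, `[[`, numeric(1), "amount")
    if (any(!is.finite(amounts)) || any(amounts < 0))
      stop("group amounts must be finite and non-negative")
  }
  structure(list(channel_names = channel_names,
                 reporter_mz = reporter_mz,
                 impurity_matrix = impurity_matrix,
                 empty_channels = as.character(empty_channels),
                 interference_only_channels = as.character(interference_only_channels),
                 groups = groups),
            class = "channel_layout")
}

#' @export
print.channel_layout <- function(x, ...) {
  cat("channel_layout:", length(x$channel_names), "channels\n")
  cat("  empty:", if (length(x$empty_channels)) paste(x$empty_channels, collapse = ", ") else "none", "\n")
  cat("  interference-only:", if (length(x$interference_only_channels))
    paste(x$interference_only_channels, collapse = ", ") else "none", "\n")
  for (g in names(x$groups))
    cat(sprintf("  group %-8s amount %5.1f : %s\n", g, x$groups[[g]]$amount,
                paste(x$groups[[g]]$channels, collapse = ", ")))
  invisible(x)
}

#' Peptide-carrying (non-empty) channels of a layout
#'
#' @param layout A [channel_layout()].
#' @return Character vector of channels that carry peptide material
#'   (everything except `empty_channels`). Interference-only channels carry
#'   background peptide and are therefore included.
#' @export
peptide_channels <- function(layout) {
  setdiff(layout$channel_names, layout$empty_channels)
}

#' Denominator channel set for the observed interference level
#'
#' Channels that carry the spiked proteome plus the same uniform background:
#' all peptide channels except the interference-only set.
#'
#' @param layout A [channel_layout()].
#' @return Character vector of channel names.
#' @export
oil_denominator_channels <- function(layout) {
  setdiff(peptide_channels(layout), layout$interference_only_channels)
}

#' Expected reporter ion m/z tables for common TMT plexes
#'
#' Monoisotopic reporter fragment m/z values for TMTpro 16/18-plex and
#' TMT 10/11-plex reagents.
#'
#' @param plex One of `"tmtpro16"`, `"tmtpro18"`, `"tmt10"`, `"tmt11"`.
#' @return Named numeric vector (channel -> m/z in Th) in plex order.
#' @export
tmt_reporter_mz <- function(plex = c("tmtpro16", "tmtpro18", "tmt10", "tmt11")) {
  plex <- match.arg(plex)
  pro <- c("126C" = 126.127726, "127N" = 127.124761, "127C" = 127.131081,
           "128N" = 128.128116, "128C" = 128.134436, "129N" = 129.131471,
           "129C" = 129.137790, "130N" = 130.134825, "130C" = 130.141145,
           "131N" = 131.138180, "131C" = 131.144500, "132N" = 132.141535,
           "132C" = 132.147855, "133N" = 133.144890, "133C" = 133.151210,
           "134N" = 134.148245)
  tmt <- c("126" = 126.127726, "127N" = 127.124761, "127C" = 127.131081,
           "128N" = 128.128116, "128C" = 128.134436, "129N" = 129.131471,
           "129C" = 129.137790, "130N" = 130.134825, "130C" = 130.141145,
           "131" = 131.138180)
  switch(plex,
         tmtpro16 = pro,
         tmtpro18 = c(pro, "134C" = 134.154565, "135N" = 135.151600),
         tmt10 = tmt,
         tmt11 = c(tmt[1:9], "131N" = 131.138180, "131C" = 131.144500))
}

#' Built-in two-proteome TMTpro 16-plex layout
#'
#' The controlled spike-in design used throughout the package: a constant
#' background proteome in 12 peptide channels, a label-only blank in 126C,
#' three channels (128N/129N/130N) entirely free of the spiked proteome and
#' four 3-channel groups receiving relative spike amounts 0, 18, 27 and 36,
#' i.e. pairwise design fold changes 1.5 (27/18), 4/3 (36/27) and 2 (36/18).
#' Unused plex positions (127N, 127C, 131N) are marked empty.
#'
#' @return A [channel_layout()].
#' @export
tmtpro16_twoproteome_layout <- function() {
  mz <- tmt_reporter_mz("tmtpro16")
  channel_layout(
    channel_names = names(mz),
    reporter_mz = mz,
    empty_channels = c("126C", "127N", "127C", "131N"),
    interference_only_channels = c("128N", "129N", "130N"),
    groups = list(
      "100:0"  = list(channels = c("128N", "129N", "130N"), amount = 0),
      "100:6"  = list(channels = c("128C", "129C", "130C"), amount = 18),
      "100:9"  = list(channels = c("131C", "132C", "133C"), amount = 27),
      "100:12" = list(channels = c("132N", "133N", "134N"), amount = 36)))
}

#' Pairwise design fold changes implied by a layout's group amounts
#'
#' @param layout A [channel_layout()] with at least two groups.
#' @return A data frame with columns `numerator`, `denominator`,
#'   `fold_change` for every ordered pair of groups with positive
#'   denominator amount (larger amount in the numerator).
#' @export
design_fold_changes <- function(layout) {
  if (length(layout$groups) < 2)
    stop("layout defines fewer than two groups")
  amounts <- vapply(layout$groups, `[[`, numeric(1), "amount")
  gn <- names(amounts)
  out <- list()
  for (i in seq_along(amounts)) for (j in seq_along(amounts)) {
    if (i == j || amounts[j] <= 0 || amounts[i] < amounts[j]) next
    out[[length(out) + 1L]] <- data.frame(
      numerator = gn[i], denominator = gn[j],
      fold_change = amounts[i] / amounts[j], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Read / write a channel layout as JSON
#'
#' @param path File path of the JSON layout.
#' @return `read_channel_layout()` returns a [channel_layout()];
#'   `write_channel_layout()` invisibly returns `path`.
#' @export
read_channel_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- list()
  if (!is.null(j$groups)) {
    for (g in names(j$groups))
      groups[[g]] <- list(channels = as.character(j$groups[[g]]$channels),
                          amount = as.numeric(j$groups[[g]]$amount))
  }
  imp <- NULL
  if (!is.null(j$impurity_matrix)) imp <- as.matrix(j$impurity_matrix)
  channel_layout(j$channel_names,
                 stats::setNames(as.numeric(j$reporter_mz), names(j$reporter_mz)),
                 impurity_matrix = imp,
                 empty_channels = as.character(j$empty_channels %||% character()),
                 interference_only_channels =
                   as.character(j$interference_only_channels %||% character()),
                 groups = groups)
}

#' @rdname read_channel_layout
#' @param layout A [channel_layout()].
#' @export
write_channel_layout <- function(layout, path) {
  j <- list(channel_names = layout$channel_names,
            reporter_mz = as.list(layout$reporter_mz),
            empty_channels = layout$empty_channels,
            interference_only_channels = layout$interference_only_channels,
            groups = layout$groups)
  if (!is.null(layout$impurity_matrix))
    j$impurity_matrix <- layout$impurity_matrix
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an isotopic impurity matrix from CSV
#'
#' Expects a square table with channel names as header and first column;
#' values are impurity fractions (columns = labeled channel, rows = detected
#' channel).
#'
#' @param path CSV file path.
#' @return Numeric matrix with channel dimnames.
#' @export
read_impurity_matrix <- function(path) {
  if (!file.exists(path)) stop("impurity matrix file not found: ", path)
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
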