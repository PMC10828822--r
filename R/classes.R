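KNOWN_MODIFICATIONS <- c("TMT", "TMTpro", "Phospho", "Acetyl", "Oxidation",
                         "Carbamidomethyl", "Deamidation")

parse_modifications <- function(modifications) {
  lapply(modifications, function(m) {
    if (is.na(m) || !nzchar(trimws(m))) return(character())
    toks <- trimws(strsplit(m, ";", fixed = TRUE)[[1]])
    toks <- toks[nzchar(toks)]
    name <- sub("\\s*\\(.*$", "", toks)
    ok <- vapply(name, function(nm)
      any(startsWith(nm, KNOWN_MODIFICATIONS)), logical(1))
    if (any(!ok))
      stop("unknown modification token: ", name[!ok][1])
    name
  })
}

#' Peptide features used by the empirical class tree
#'
#' Derives, per PSM, the physicochemical features over which fragmentation
#' efficiency classes are learned: the precursor charge category (charges
#' above 3 are set to 3), the number of isobaric labels on the peptide
#' (N-terminal plus lysine labels, counted from the modification string),
#' presence/absence of histidine, arginine, lysine, glutamate and aspartate,
#' and an extra-charge flag marking precursors whose charge exceeds the
#' allowance of one proton plus the number of basic residues
#' (`charge > #R + #H + 1`). Variable modifications other than the isobaric
#' label (e.g. Phospho, Acetyl) yield additional boolean columns
#' `has_mod_<name>`.
#'
#' @param psms PSM data frame with `sequence`, `modifications`, `charge`.
#' @return Data frame of feature columns (`charge_cat`, `n_labels`, `has_H`,
#'   `has_R`, `has_K`, `has_E`, `has_D`, `extra_charge`, optional
#'   `has_mod_*`), one row per PSM.
#' @export
featurize_peptides <- function(psms) {
  seqs <- toupper(psms$sequence)
  count_aa <- function(aa) {
    vapply(gregexpr(aa, seqs, fixed = TRUE), function(g)
      if (g[1] == -1L) 0L else length(g), integer(1))
  }
  nH <- count_aa("H"); nR <- count_aa("R"); nK <- count_aa("K")
  nE <- count_aa("E"); nD <- count_aa("D")
  mods <- parse_modifications(psms$modifications)
  n_labels <- vapply(mods, function(m) sum(startsWith(m, "TMT")), integer(1))
  out <- data.frame(
    charge_cat = pmin(pmax(as.integer(psms$charge), 1L), 3L),
    n_labels = n_labels,
    has_H = nH > 0, has_R = nR > 0, has_K = nK > 0,
    has_E = nE > 0, has_D = nD > 0,
    extra_charge = psms$charge > nR + nH + 1L)
  other <- sort(unique(unlist(lapply(mods, function(m)
    m[!startsWith(m, "TMT")]))))
  for (nm in other)
    out[[paste0("has_mod_", nm)]] <-
      vapply(mods, function(m) nm %in% m, logical(1))
  out
}

#' Fragmentation-efficiency response of a PSM table
#'
#' The per-PSM log reporter yield per unit of precursor fragment current:
#' `log(total reporter intensity / (PIC * PPF))`. This is the quantity whose
#' within-class variance the class tree minimizes.
#'
#' @param metrics PSM data frame with `pic` and `ppf` columns.
#' @return Numeric vector (non-finite where undefined).
#' @export
class_response <- function(metrics) {
  total <- rowSums(reporter_matrix(metrics), na.rm = TRUE)
  log(total / (metrics$pic * metrics$ppf))
}

feature_display <- c(charge_cat = "Charge", n_labels = "Labels",
                     has_H = "H", has_R = "R", has_K = "K", has_E = "E",
                     has_D = "D", extra_charge = "Extra")

split_label <- function(var, threshold, left) {
  disp <- if (var %in% names(feature_display)) feature_display[[var]]
          else sub("^has_mod_", "", var)
  if (startsWith(var, "has_") || var == "extra_charge")
    paste0(disp, if (left) "-" else "+")
  else
    paste0(disp, if (left) "<=" else ">", threshold)
}

#' Fit the empirical peptide-class decision tree
#'
#' Grows a binary decision tree by greedy recursive partitioning: at each
#' node every admissible binary split over every feature variable is
#' evaluated (ordinal variables by `<= threshold`, booleans by level), and
#' the split minimizing the total within-child variance of the response
#' (the sum of the two children's sample variances) is chosen. Splits
#' producing a child with `<= min_leaf` observations are rejected; growth
#' stops when no admissible split reduces the within-node variance by at
#' least the fraction `min_improvement`. The improvement floor matters:
#' chance splits of a homogeneous node always reduce the within sum of
#' squares by a little (of order 1/n), whereas a genuine difference in
#' fragmentation efficiency removes the whole between-class variance share,
#' typically tens of percent. Ties are broken by a fixed variable order
#' (Charge, Labels, H, R, K, E, D, Extra, then modification features), then
#' by the smallest threshold, making refits bit-identical.
#'
#' @param features Feature data frame from [featurize_peptides()].
#' @param response Numeric response vector (see [class_response()]).
#' @param min_leaf Minimum observations a leaf must exceed (default 100).
#' @param min_improvement Minimum relative reduction of the within-node sum
#'   of squares a split must achieve (default 0.05).
#' @param trim_mads Gross response outliers further than this many MADs from
#'   the median are excluded from tree training (they are still routed to a
#'   class by [assign_class()]); `Inf` disables trimming. Plain variance is
#'   extremely outlier-sensitive, so without trimming a handful of aberrant
#'   scans can mask real class structure.
#' @return An object of class `pep_class_tree`.
#' @export
fit_class_tree <- function(features, response, min_leaf = 100,
                           min_improvement = 0.05, trim_mads = 5) {
  stopifnot(nrow(features) == length(response))
  keep <- is.finite(response)
  if (is.finite(trim_mads) && sum(keep) > 3) {
    med <- stats::median(response[keep])
    md <- stats::mad(response[keep])
    if (md > 0)
      keep <- keep & abs(response - med) <= trim_mads * md
  }
  features <- features[keep, , drop = FALSE]
  response <- response[keep]
  var_order <- c(intersect(names(feature_display), names(features)),
                 sort(grep("^has_mod_", names(features), value = TRUE)))
  n <- length(response)
  single <- FALSE
  if (n < 2 * min_leaf) {
    warning("fewer than 2 * min_leaf PSMs; fitting a single-class tree")
    single <- TRUE
  }

  grow <- function(idx, path) {
    y <- response[idx]
    leaf <- function() list(leaf = TRUE,
                            label = if (length(path)) paste(path, collapse = "/") else "all",
                            n = length(idx), mean = mean(y))
    if (single) return(leaf())
    # both children must exceed min_leaf, so at least 2*min_leaf+2 rows
    if (length(idx) < 2 * min_leaf + 2) return(leaf())
    sse <- function(v) { m <- mean(v); sum((v - m)^2) }
    node_sse <- sse(y)
    if (node_sse <= 0) return(leaf())
    best <- NULL
    for (var in var_order) {
      x <- features[[var]][idx]
      if (is.logical(x)) thresholds <- if (length(unique(x)) > 1) 0 else numeric(0)
      else { u <- sort(unique(x)); thresholds <- u[-length(u)] }
      for (th in thresholds) {
        left <- if (is.logical(x)) !x else x <= th
        nl <- sum(left); nr <- length(left) - nl
        if (nl <= min_leaf || nr <= min_leaf) next
        s <- sse(y[left]) + sse(y[!left])
        # require a material variance reduction: chance splits of a
        # homogeneous node reduce the within sum of squares by O(1/n),
        # genuine class structure by the between-class variance share
        if (s > node_sse * (1 - min_improvement)) next
        if (is.null(best) || s < best$s - 1e-12 * max(best$s, 1))
          best <- list(var = var, th = th, s = s, left = left)
      }
    }
    if (is.null(best)) return(leaf())
    list(leaf = FALSE, var = best$var, threshold = best$th,
         n = length(idx),
         left = grow(idx[best$left],
                     c(path, split_label(best$var, best$th, TRUE))),
         right = grow(idx[!best$left],
                      c(path, split_label(best$var, best$th, FALSE))))
  }
  root <- grow(seq_len(n), character())
  structure(list(root = root, var_order = var_order, min_leaf = min_leaf,
                 n_train = n), class = "pep_class_tree")
}

collect_leaves <- function(node) {
  if (isTRUE(node$leaf))
    return(data.frame(label = node$label, n = node$n, mean = node$mean))
  rbind(collect_leaves(node$left), collect_leaves(node$right))
}

#' @export
print.pep_class_tree <- function(x, ...) {
  lv <- collect_leaves(x$root)
  cat("pep_class_tree:", nrow(lv), "class(es) over", x$n_train, "PSMs\n")
  for (i in seq_len(nrow(lv)))
    cat(sprintf("  %-30s n=%6d  mean=%8.4f\n", lv$label[i], lv$n[i], lv$mean[i]))
  invisible(x)
}

#' Leaf summary of a fitted class tree
#'
#' @param tree A `pep_class_tree`.
#' @return Data frame with columns `label`, `n`, `mean`.
#' @export
class_tree_leaves <- function(tree) collect_leaves(tree$root)

#' Assign empirical peptide classes
#'
#' Routes feature vectors through a fitted tree; every feature vector
#' reaches exactly one leaf (the tree partitions the full feature space).
#'
#' @param tree A `pep_class_tree` from [fit_class_tree()].
#' @param features Feature data frame from [featurize_peptides()].
#' @return Character vector of class labels, one per row of `features`.
#' @export
assign_class <- function(tree, features) {
  out <- character(nrow(features))
  route <- function(node, idx) {
    if (!length(idx)) return()
    if (isTRUE(node$leaf)) { out[idx] <<- node$label; return() }
    x <- features[[node$var]][idx]
    left <- if (is.logical(x)) !x else x <= node$threshold
    route(node$left, idx[left])
    route(node$right, idx[!left])
  }
  route(tree$root, seq_len(nrow(features)))
  out
}
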