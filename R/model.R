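#' Assemble the design matrix of an interference regression model
#'
#' Two model forms are supported, both with the intercept fixed at zero and
#' interaction (one-slope-per-level) encoding of categorical variables:
#' \describe{
#'   \item{`general`}{Response `y` = total reporter intensity of the MS2
#'     scan; regressors: `precursor = PIC * PPF` with one slope per
#'     empirical peptide class, `nonprecursor = PIC * (1 - PPF)` with one
#'     slope per charge category, and a single `noiseEstimate` column.}
#'   \item{`ground_truth`}{Response `y` = summed reporter intensity of the
#'     layout's interference-only channels (callers restrict the rows to
#'     spiked-proteome PSMs); regressors: `nonprecursor = TIW * (1 - PPF)`
#'     per charge category plus `noiseEstimate`. This model predicts the
#'     directly observable interference and exists for validation against
#'     the observed interference level.}
#' }
#' Charge categories observed fewer than `min_charge_obs` times are merged
#' into the nearest category before encoding. PSMs missing any required
#' metric are excluded and counted.
#'
#' @param metrics PSM data frame carrying `ppf`, `tiw`, `pic`,
#'   `noise_estimate`, `charge` and reporter columns; for the general model
#'   also a `pep_class` column.
#' @param model `"general"` or `"ground_truth"`.
#' @param layout A [channel_layout()] (required for `ground_truth`).
#' @param min_charge_obs Minimum observations per charge category.
#' @return List with `y`, design matrix `X`, `families` (named character
#'   vector mapping columns to `"precursor"`, `"nonprecursor"` or
#'   `"noise"`), `rows` (row indices of `metrics` used), `n_excluded`, and
#'   `charge_cat` / `pep_class` level vectors.
#' @export
build_design <- function(metrics, model = c("general", "ground_truth"),
                         layout = NULL, min_charge_obs = 25) {
  model <- match.arg(model)
  rep_mat <- reporter_matrix(metrics, layout)
  if (model == "general") {
    y_all <- rowSums(rep_mat, na.rm = TRUE)
    base_term <- metrics$pic
  } else {
    if (is.null(layout) || !length(layout$interference_only_channels))
      stop("ground_truth model requires a layout with interference-only channels")
    icols <- intersect(layout$interference_only_channels, colnames(rep_mat))
    y_all <- rowSums(rep_mat[, icols, drop = FALSE], na.rm = TRUE)
    base_term <- metrics$tiw
  }
  need <- is.finite(metrics$ppf) & is.finite(base_term) &
    is.finite(metrics$noise_estimate) & is.finite(y_all) &
    is.finite(metrics$charge)
  if (model == "general")
    need <- need & !is.na(metrics$pep_class)
  rows <- which(need)
  n_excluded <- nrow(metrics) - length(rows)
  m <- metrics[rows, , drop = FALSE]
  y <- y_all[rows]

  charge_cat <- pmin(pmax(as.integer(m$charge), 1L), 3L)
  tab <- table(charge_cat)
  levels_present <- as.integer(names(tab))
  for (lv in levels_present[tab < min_charge_obs]) {
    others <- setdiff(unique(charge_cat), lv)
    if (!length(others)) break
    nearest <- others[which.min(abs(others - lv))]
    charge_cat[charge_cat == lv] <- nearest
  }
  charge_f <- factor(charge_cat)

  nonprec <- (if (model == "general") m$pic else m$tiw) * (1 - m$ppf)
  X_np <- sapply(levels(charge_f), function(lv)
    nonprec * (charge_f == lv))
  if (is.null(dim(X_np))) X_np <- matrix(X_np, nrow = length(y))
  colnames(X_np) <- paste0("nonprecursor.charge", levels(charge_f))

  if (model == "general") {
    class_f <- factor(m$pep_class)
    prec <- m$pic * m$ppf
    X_p <- sapply(levels(class_f), function(lv) prec * (class_f == lv))
    if (is.null(dim(X_p))) X_p <- matrix(X_p, nrow = length(y))
    colnames(X_p) <- paste0("precursor.class.", levels(class_f))
    X <- cbind(X_p, X_np, noiseEstimate = m$noise_estimate)
    families <- stats::setNames(
      c(rep("precursor", ncol(X_p)), rep("nonprecursor", ncol(X_np)), "noise"),
      colnames(X))
  } else {
    X <- cbind(X_np, noiseEstimate = m$noise_estimate)
    families <- stats::setNames(
      c(rep("nonprecursor", ncol(X_np)), "noise"), colnames(X))
  }
  list(y = as.numeric(y), X = X, families = families, rows = rows,
       n_excluded = n_excluded, model = model,
       charge_cat = charge_cat,
       pep_class = if (model == "general") as.character(m$pep_class) else NULL)
}

#' Robust fit of an interference regression model
#'
#' Fits the zero-intercept linear model by iteratively reweighted least
#' squares M-estimation with the Tukey bisquare psi (tuning constant 4.685)
#' and MAD residual scale, via [MASS::rlm()]. Reporter-signal noise is
#' strongly multiplicative, so after a pilot fit the observations are
#' additionally case-weighted by the inverse squared fitted value
#' (`variance_weight_rounds` rounds); this variance stabilization removes
#' the systematic term-dependent bias that a single global residual scale
#' produces on data whose error grows with the signal. Set
#' `variance_weight_rounds = 0` for the plain unweighted M-fit.
#' Rank-deficient designs drop aliased columns with a warning;
#' non-convergent fits return the last iterate flagged.
#'
#' @param design Design list from [build_design()].
#' @param raw_file,compensation_voltage Identifiers stored in the result.
#' @param maxit Maximum IRLS iterations (default 50).
#' @param acc Convergence tolerance on the scaled coefficient change
#'   (default 1e-8).
#' @param k Bisquare tuning constant (default 4.685).
#' @param variance_weight_rounds Rounds of inverse-squared-fitted-value
#'   case weighting after the pilot fit (default 2).
#' @return An object of class `interference_fit`: coefficients, column
#'   families, the precursor coefficient subset, final robust weights,
#'   robust residual scale, convergence flag and observation count.
#' @export
fit_robust <- function(design, raw_file = NA_character_,
                       compensation_voltage = NA_real_,
                       maxit = 50, acc = 1e-8, k = 4.685,
                       variance_weight_rounds = 2) {
  X <- design$X
  y <- design$y
  if (nrow(X) <= ncol(X))
    stop("more model columns than observations")
  qrX <- qr(X)
  dropped <- character()
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    warning("dropping aliased design column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  quiet_rlm <- function(...) withCallingHandlers(
    MASS::rlm(..., psi = MASS::psi.bisquare, c = k,
              scale.est = "MAD", maxit = maxit, acc = acc),
    warning = function(w) {
      if (grepl("failed to converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  fit <- quiet_rlm(x = X, y = y)
  floor_fit <- stats::quantile(y[y > 0], 0.01, names = FALSE)
  if (!is.finite(floor_fit) || floor_fit <= 0) floor_fit <- 1e-6
  for (r in seq_len(variance_weight_rounds)) {
    fitted <- pmax(as.numeric(X %*% fit$coefficients), floor_fit)
    fit <- quiet_rlm(x = X, y = y, weights = 1 / fitted^2,
                     wt.method = "inv.var")
  }
  families <- design$families[colnames(X)]
  coef <- stats::setNames(as.numeric(fit$coefficients), colnames(X))
  converged <- isTRUE(fit$converged)
  # an exact interpolation has zero residual scale; rlm cannot flag
  # convergence there, but the solution is final
  if (!converged &&
      max(abs(y - as.numeric(X %*% coef))) <= 1e-8 * max(abs(y)))
    converged <- TRUE
  structure(list(raw_file = raw_file,
                 compensation_voltage = compensation_voltage,
                 model = design$model,
                 coef = coef, families = families,
                 precursor_coef_names = names(coef)[families == "precursor"],
                 dropped = dropped,
                 robust_weights = as.numeric(fit$w),
                 scale = fit$s, converged = converged,
                 n_obs = length(y)),
            class = "interference_fit")
}

#' @export
print.interference_fit <- function(x, ...) {
  cat(sprintf("interference_fit (%s model), raw file %s, n = %d, %s\n",
              x$model, x$raw_file, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$coef, 6))
  invisible(x)
}

#' Estimated interference level of PSMs under a fitted model
#'
#' `EIL = clamp(1 - (x_precursor' b_precursor) / (x' b), 0, 1)`: one minus
#' the fitted precursor share of the fitted total reporter intensity. PSMs
#' whose fitted total is non-positive get a missing EIL.
#'
#' @param fit An `interference_fit` from [fit_robust()] (general model).
#' @param design The design list the rows come from (columns must cover the
#'   fit's coefficients).
#' @return Numeric vector of EIL fractions, aligned with `design$rows`.
#' @export
compute_eil <- function(fit, design) {
  cols <- names(fit$coef)
  X <- design$X[, cols, drop = FALSE]
  total <- as.numeric(X %*% fit$coef)
  pcols <- fit$precursor_coef_names
  if (!length(pcols))
    stop("fit has no precursor coefficients; EIL requires the general model")
  prec <- as.numeric(X[, pcols, drop = FALSE] %*% fit$coef[pcols])
  eil <- 1 - prec / total
  eil[total <= 0] <- NA_real_
  pmin(pmax(eil, 0), 1)
}

#' Decompose fitted reporter signal into term-family contributions
#'
#' Shares of the total fitted reporter signal attributable to the
#' precursor, visible nonprecursor, and noise term families; shares sum
#' to 1.
#'
#' @param fit An `interference_fit`.
#' @param design Design list with matching columns.
#' @return Named numeric vector of shares (`precursor`, `nonprecursor`,
#'   `noise`; `precursor` absent for the ground-truth model).
#' @export
decompose_signal <- function(fit, design) {
  cols <- names(fit$coef)
  X <- design$X[, cols, drop = FALSE]
  contrib <- sweep(X, 2, fit$coef, `*`)
  tot <- sum(contrib)
  fams <- unique(fit$families)
  out <- vapply(fams, function(f)
    sum(contrib[, names(fit$families)[fit$families == f], drop = FALSE]) / tot,
    numeric(1))
  stats::setNames(out, fams)
}

#' Fit the interference model per raw file (and compensation voltage)
#'
#' Splits the metrics table by raw file - and, when a non-missing
#' `compensation_voltage` column is present, additionally by voltage - fits
#' each stratum with [fit_robust()], and assembles per-PSM estimated
#' interference levels.
#'
#' @param metrics Metrics table (see [build_design()] requirements).
#' @param model `"general"` or `"ground_truth"`.
#' @param layout A [channel_layout()].
#' @param ... Passed to [fit_robust()].
#' @return List with `fits` (named list of `interference_fit`) and `eil`
#'   (numeric vector aligned with `metrics` rows; `NA` where no fit
#'   applies; only for the general model).
#' @export
fit_interference_model <- function(metrics, model = "general", layout = NULL,
                                   ...) {
  strata <- metrics$raw_file
  if ("compensation_voltage" %in% names(metrics) &&
      any(is.finite(metrics$compensation_voltage)))
    strata <- paste(strata, metrics$compensation_voltage, sep = "@")
  fits <- list()
  eil <- rep(NA_real_, nrow(metrics))
  for (st in unique(strata)) {
    sel <- which(strata == st)
    design <- build_design(metrics[sel, , drop = FALSE], model = model,
                           layout = layout)
    fit <- fit_robust(design, raw_file = metrics$raw_file[sel[1]],
                      compensation_voltage =
                        if ("compensation_voltage" %in% names(metrics))
                          metrics$compensation_voltage[sel[1]] else NA_real_,
                      ...)
    fits[[st]] <- fit
    if (model == "general")
      eil[sel[design$rows]] <- compute_eil(fit, design)
  }
  list(fits = fits, eil = if (model == "general") eil else NULL)
}

#' Serialize fitted interference models to JSON
#'
#' @param fits Named list of `interference_fit` objects.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fits, path) {
  j <- lapply(fits, function(f)
    list(raw_file = f$raw_file,
         compensation_voltage = f$compensation_voltage,
         model = f$model, coef = as.list(f$coef),
         families = as.list(f$families),
         scale = f$scale, converged = f$converged, n_obs = f$n_obs,
         weights_summary = as.list(summary(f$robust_weights))))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
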