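#' Configuration for the two-proteome multiplex simulator
#'
#' Captures the study conditions of a controlled two-proteome spike-in
#' design with known ground-truth interference: a constant-abundance
#' background proteome in all peptide channels, a spiked proteome whose
#' relative amounts across four 3-channel groups follow the layout's design
#' (defaults 0 : 18 : 27 : 36, i.e. fold changes 1.5, 4/3, 2), three
#' channels free of the spiked proteome, and a hidden-noise interference
#' component that is present in reporter signal but absent from the emitted
#' MS1 peak lists.
#'
#' @param seed Integer seed; fully determines the output.
#' @param n_runs Number of simulated raw files.
#' @param psms_per_run PSMs per raw file.
#' @param layout A [channel_layout()] with groups; default the built-in
#'   two-proteome TMTpro design.
#' @param background_to_spike_mass_ratio Mass ratio of background to spiked
#'   proteome (default 10, i.e. a spiked-PSM share of 1/11).
#' @param n_spike_proteins,n_background_proteins Protein counts per species.
#' @param class_vars Boolean feature columns (of [featurize_peptides()])
#'   whose combinations define the planted fragmentation-efficiency classes.
#' @param beta_precursor Named numeric vector of precursor slopes (reporter
#'   yield per unit `PIC * PPF`), one per planted class combination; names
#'   are `;`-joined `var=value` strings (see [planted_class_labels()]).
#' @param beta_nonprecursor Named numeric vector of visible-interference
#'   slopes by charge category (`"2"`, `"3"`).
#' @param beta_noise Slope of the noise-estimate regressor.
#' @param tiw_scale Ratio of total MS1 isolation-window intensity to PIC.
#' @param pic_meanlog,pic_sdlog Lognormal law of the peptide ion current.
#' @param ppf_shape Beta-law shape parameters of the precursor purity
#'   fraction.
#' @param window_noise_meanlog,window_noise_sdlog Lognormal law of the MS1
#'   window noise values.
#' @param y_sdlog Multiplicative lognormal measurement noise on the total
#'   reporter signal (log-scale sd; median 1).
#' @param protein_ppf_sd,protein_noise_sd Protein-level random effects:
#'   peptides of one protein share an abundance and elution context, so
#'   their purity and local noise floor are correlated. `protein_ppf_sd`
#'   shifts the logit of the purity draw, `protein_noise_sd` is a log-scale
#'   multiplier on the window noise.
#' @param channel_jitter_phi Additive Poisson-like channel jitter: a channel
#'   value `v` receives noise of standard deviation `sqrt(v * phi)`.
#' @param outlier_fraction,outlier_factor Share of PSMs whose total signal
#'   is grossly inflated, and the inflation factor.
#' @param interference_fraction When non-`NULL`, the per-PSM interference
#'   share of total reporter signal is drawn from a Beta law with this mean
#'   (and concentration `interference_concentration`), and the hidden-noise
#'   component absorbs the remainder after the visible part (PPF draws are
#'   raised where needed to keep it non-negative). The share cannot be
#'   pinned to a single exact value for every PSM: that would make the
#'   interference signal exactly proportional to the precursor signal and
#'   the regression model unidentifiable (the noise column becomes an exact
#'   linear combination of the other columns).
#' @param interference_concentration Beta concentration (a+b) of the
#'   per-PSM interference share when `interference_fraction` is set
#'   (default 40, i.e. sd about 0.07 at a mean of 0.3).
#' @param mz_range,rt_range Precursor m/z (Th) and retention time (min)
#'   ranges.
#' @param gridsize Density grid nodes per axis.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_runs = 1L, psms_per_run = 5000L,
                       layout = tmtpro16_twoproteome_layout(),
                       background_to_spike_mass_ratio = 10,
                       n_spike_proteins = 80L, n_background_proteins = 600L,
                       class_vars = "has_R",
                       beta_precursor = c("has_R=TRUE" = 0.55,
                                          "has_R=FALSE" = 1.15),
                       beta_nonprecursor = c("2" = 0.9, "3" = 0.65),
                       beta_noise = 800,
                       tiw_scale = 1.8,
                       pic_meanlog = log(2e5), pic_sdlog = 0.9,
                       ppf_shape = c(12, 2),
                       window_noise_meanlog = log(5000),
                       window_noise_sdlog = 0.5,
                       y_sdlog = 0.3,
                       protein_ppf_sd = 0.7, protein_noise_sd = 0.4,
                       channel_jitter_phi = 100,
                       outlier_fraction = 0.05, outlier_factor = 100,
                       interference_fraction = NULL,
                       interference_concentration = 40,
                       mz_range = c(400, 1200), rt_range = c(10, 110),
                       gridsize = 200) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulator configuration
#'
#' Checks positivity of all rate and scale parameters and that the layout's
#' group amounts reproduce the intended design fold changes (the largest
#' three pairwise ratios of the default design are 2, 1.5 and 4/3).
#'
#' @param cfg A `sim_config`.
#' @return Invisibly, the validated config; errors otherwise.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(cfg$psms_per_run >= 1, cfg$n_runs >= 1,
            cfg$background_to_spike_mass_ratio > 0,
            all(cfg$beta_precursor > 0), all(cfg$beta_nonprecursor >= 0),
            cfg$beta_noise >= 0, cfg$tiw_scale > 0,
            cfg$y_sdlog >= 0, cfg$channel_jitter_phi >= 0,
            cfg$outlier_fraction >= 0, cfg$outlier_fraction < 1,
            cfg$outlier_factor > 0)
  if (!is.null(cfg$interference_fraction))
    stopifnot(cfg$interference_fraction > 0, cfg$interference_fraction < 0.8,
              cfg$interference_concentration > 2)
  fc <- design_fold_changes(cfg$layout)
  if (is.null(fc) || nrow(fc) < 1)
    stop("layout groups define no positive design fold change")
  invisible(cfg)
}

#' Class combination labels of planted fragmentation-efficiency classes
#'
#' @param features Feature data frame from [featurize_peptides()].
#' @param class_vars Boolean feature columns defining the planted classes.
#' @return Character vector of `;`-joined `var=value` labels.
#' @export
planted_class_labels <- function(features, class_vars) {
  parts <- lapply(class_vars, function(v)
    paste0(v, "=", features[[v]]))
  do.call(paste, c(parts, sep = ";"))
}

AA_INTERNAL <- c("A", "G", "I", "L", "P", "S", "T", "V", "F", "Y", "W",
                 "N", "Q", "M", "C", "H", "E", "D", "R", "K")
AA_WEIGHTS <- c(rep(1, 11), rep(0.7, 4), 0.6, 0.9, 0.9, 0.15, 0.15)

random_peptides <- function(n) {
  lens <- sample(7:18, n, replace = TRUE)
  term <- sample(c("K", "R"), n, replace = TRUE)
  vapply(seq_len(n), function(i)
    paste0(paste(sample(AA_INTERNAL, lens[i] - 1L, replace = TRUE,
                        prob = AA_WEIGHTS), collapse = ""), term[i]),
    character(1))
}

peptide_modifications <- function(seqs) {
  vapply(seqs, function(s) {
    kpos <- which(strsplit(s, "")[[1]] == "K")
    paste(c("TMTpro (N-term)",
            if (length(kpos)) paste0("TMTpro (K", kpos, ")")),
          collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a two-proteome multiplex dataset with known ground truth
#'
#' Draws PSMs of a spiked and a background proteome, generates their total
#' reporter signal from the generative linear model (class-specific
#' precursor slopes on `PIC * PPF`, charge-specific slopes on the visible
#' nonprecursor term, and a noise slope on the hidden-interference
#' regressor), splits the signal across channels according to the group
#' design (precursor part) and uniformly (interference part), and emits MS1
#' snapshots from which PPF and TIW recompute exactly. The hidden-noise
#' interference component is present in reporter signal but absent from the
#' emitted MS1 peak lists - only the peaks' noise values betray it.
#'
#' @param cfg A [sim_config()].
#' @return List with `psms` (PSM table), `ms1` (named list of `ms1_run`),
#'   `truth` (per-PSM ground truth: species, protein, planted class, true
#'   interference fraction, true OIL, outlier flag, expected signal parts)
#'   and `betas` (the planted coefficient sets).
#' @export
simulate_dataset <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  layout <- cfg$layout
  pep_ch <- peptide_channels(layout)
  amounts <- rep(0, length(pep_ch)); names(amounts) <- pep_ch
  for (g in layout$groups)
    amounts[g$channels] <- g$amount
  spike_share <- amounts / sum(amounts)
  bg_share <- rep(1 / length(pep_ch), length(pep_ch))
  names(bg_share) <- pep_ch

  psm_list <- list(); ms1_runs <- list(); truth_list <- list()
  for (r in seq_len(cfg$n_runs)) {
    rf <- sprintf("sim_run%02d", r)
    n <- cfg$psms_per_run
    n_pep <- max(20L, ceiling(n * 0.6))
    p_spike <- 1 / (1 + cfg$background_to_spike_mass_ratio)
    pep_species <- ifelse(stats::runif(n_pep) < p_spike, "spike", "background")
    pep_seq <- random_peptides(n_pep)
    pep_mod <- peptide_modifications(pep_seq)
    pep_charge <- sample(2:4, n_pep, replace = TRUE,
                         prob = c(0.52, 0.36, 0.12))
    pep_protein <- ifelse(
      pep_species == "spike",
      sprintf("SPIKE_P%03d", sample.int(cfg$n_spike_proteins, n_pep, TRUE)),
      sprintf("BG_P%03d", sample.int(cfg$n_background_proteins, n_pep, TRUE)))
    pep_mz <- stats::runif(n_pep, cfg$mz_range[1], cfg$mz_range[2])
    # retention times from a mixture so the peptide density varies smoothly
    cl <- stats::runif(n_pep) < 0.45
    pep_rt <- ifelse(cl,
                     stats::rnorm(n_pep, mean = cfg$rt_range[1] +
                                    c(0.3, 0.65)[1 + (stats::runif(n_pep) < 0.5)] *
                                    diff(cfg$rt_range), sd = 0.08 * diff(cfg$rt_range)),
                     stats::runif(n_pep, cfg$rt_range[1], cfg$rt_range[2]))
    pep_rt <- pmin(pmax(pep_rt, cfg$rt_range[1]), cfg$rt_range[2])

    idx <- sample.int(n_pep, n, replace = TRUE)
    ord <- order(pep_rt[idx], idx)
    idx <- idx[ord]
    rt <- pep_rt[idx]; mz <- pep_mz[idx]
    charge <- pep_charge[idx]
    psms <- data.frame(
      psm_id = sprintf("%s:%d", rf, 10L * seq_len(n) + 5L),
      raw_file = rf, ms2_scan = 10L * seq_len(n) + 5L,
      sequence = pep_seq[idx], modifications = pep_mod[idx],
      charge = charge, precursor_mz = mz, retention_time_min = rt,
      isolation_width = 0.7, species_tag = pep_species[idx],
      protein_id = pep_protein[idx], compensation_voltage = NA_real_,
      ms3_quantified = FALSE, stringsAsFactors = FALSE)

    feats <- featurize_peptides(psms)
    class_lab <- planted_class_labels(feats, cfg$class_vars)
    missing_beta <- setdiff(unique(class_lab), names(cfg$beta_precursor))
    if (length(missing_beta))
      stop("beta_precursor lacks entries for planted class(es): ",
           paste(missing_beta, collapse = ", "))
    beta_p <- unname(cfg$beta_precursor[class_lab])
    charge_cat <- as.character(pmin(charge, 3L))
    beta_np <- unname(cfg$beta_nonprecursor[charge_cat])
    if (any(is.na(beta_np)))
      stop("beta_nonprecursor lacks entries for observed charge categories")

    # protein random effects: peptides of one protein share abundance and
    # elution context, hence correlated purity and local noise floors
    prots <- unique(pep_protein)
    u_ppf <- stats::setNames(stats::rnorm(length(prots)), prots)
    u_noise <- stats::setNames(stats::rnorm(length(prots)), prots)
    psm_prot <- psms$protein_id

    pic <- stats::rlnorm(n, cfg$pic_meanlog, cfg$pic_sdlog)
    ppf <- stats::rbeta(n, cfg$ppf_shape[1], cfg$ppf_shape[2])
    ppf <- stats::plogis(stats::qlogis(ppf) +
                           cfg$protein_ppf_sd * u_ppf[psm_prot])
    ppf <- pmin(pmax(ppf, 0.05), 0.995)
    f_i <- NULL
    if (!is.null(cfg$interference_fraction)) {
      conc <- cfg$interference_concentration
      f_i <- stats::rbeta(n, cfg$interference_fraction * conc,
                          (1 - cfg$interference_fraction) * conc)
      f_i <- pmin(pmax(f_i, 0.02), 0.75)
      ppf_min <- 1 / (1 + (f_i / (1 - f_i)) * beta_p / beta_np)
      ppf <- pmax(ppf, pmin(ppf_min * 1.05, 0.99))
    }

    # run-specific peptide density over the drawn features, exactly as the
    # analysis pipeline will rebuild it
    ufeat <- unique_peptide_features(psms)
    grid <- build_density(ufeat$mz, ufeat$rt, gridsize = cfg$gridsize)
    dens <- interpolate_density(grid, mz, rt)

    prec_term <- pic * ppf
    nonprec_term <- pic * (1 - ppf)
    y_prec <- beta_p * prec_term
    y_vis <- beta_np * nonprec_term
    if (!is.null(cfg$interference_fraction)) {
      noise_est <- ((f_i / (1 - f_i)) * y_prec - y_vis) / cfg$beta_noise
      noise_est <- pmax(noise_est, 0)
      window_noise <- noise_est / dens
    } else {
      window_noise <- stats::rlnorm(n, cfg$window_noise_meanlog,
                                    cfg$window_noise_sdlog) *
        exp(cfg$protein_noise_sd * u_noise[psm_prot])
      noise_est <- window_noise * dens
    }
    y_noise <- cfg$beta_noise * noise_est
    y_exp <- y_prec + y_vis + y_noise
    y_int <- y_vis + y_noise
    true_frac <- y_int / y_exp

    eps <- stats::rlnorm(n, 0, cfg$y_sdlog)
    outlier <- stats::runif(n) < cfg$outlier_fraction
    y_meas <- y_exp * eps * ifelse(outlier, cfg$outlier_factor, 1)

    share <- matrix(bg_share, nrow = n, ncol = length(pep_ch), byrow = TRUE)
    is_spike <- psms$species_tag == "spike"
    share[is_spike, ] <- matrix(spike_share, nrow = sum(is_spike),
                                ncol = length(pep_ch), byrow = TRUE)
    frac_prec <- y_prec / y_exp
    rep_mat <- y_meas * (frac_prec * share + (1 - frac_prec) / length(pep_ch))
    if (cfg$channel_jitter_phi > 0) {
      # Poisson-like allocation jitter: perturbs the channel split of each
      # scan while preserving the scan's total (total-signal noise is
      # already modeled by the multiplicative term above)
      jit <- matrix(stats::rnorm(length(rep_mat)), nrow = n)
      tot0 <- rowSums(rep_mat)
      rep_mat <- pmax(rep_mat + jit * sqrt(rep_mat * cfg$channel_jitter_phi), 0)
      rep_mat <- rep_mat * (tot0 / pmax(rowSums(rep_mat), 1e-300))
    }
    colnames(rep_mat) <- pep_ch
    for (ch in pep_ch)
      psms[[paste0("reporter_", ch)]] <- rep_mat[, ch]
    for (ch in layout$empty_channels)
      psms[[paste0("reporter_", ch)]] <- 0
    psms$tic <- pic + rowSums(rep_mat)

    # MS1 snapshots: both bordering scans carry the precursor cluster plus a
    # visible contaminant peak; the hidden-noise component never appears as
    # a peak, only as the peaks' noise values
    tiw <- cfg$tiw_scale * pic
    p_win <- tiw * ppf
    b_win <- tiw * (1 - ppf)
    iso_off <- NEUTRON_MASS / charge
    iso_in <- iso_off <= psms$isolation_width / 2 - 1e-9
    main_int <- ifelse(iso_in, 0.78 * p_win, p_win)
    iso_int <- p_win - main_int
    d1 <- stats::runif(n, 0.02, 0.06)
    d2 <- stats::runif(n, 0.02, 0.06)

    k <- 2L + as.integer(iso_in)
    pk_psm <- rep(seq_len(n), k)
    pk_mz <- pk_int <- numeric(length(pk_psm))
    pos <- 1L
    for (i in seq_len(n)) {
      if (iso_in[i]) {
        pk_mz[pos:(pos + 2L)] <- c(mz[i], mz[i] + 0.17, mz[i] + iso_off[i])
        pk_int[pos:(pos + 2L)] <- c(main_int[i], b_win[i], iso_int[i])
        pos <- pos + 3L
      } else {
        pk_mz[pos:(pos + 1L)] <- c(mz[i], mz[i] + 0.17)
        pk_int[pos:(pos + 1L)] <- c(main_int[i], b_win[i])
        pos <- pos + 2L
      }
    }
    ms1_df <- data.frame(
      raw_file = rf,
      scan_number = c(10L * pk_psm, 10L * pk_psm + 9L),
      retention_time_min = c(rt[pk_psm] - d1[pk_psm], rt[pk_psm] + d2[pk_psm]),
      mz = c(pk_mz, pk_mz),
      intensity = c(pk_int, pk_int),
      noise = c(window_noise[pk_psm], window_noise[pk_psm]))
    ms1_runs[[rf]] <- as_ms1_runs(ms1_df)[[rf]]

    exp_mat <- y_exp * (frac_prec * share + (1 - frac_prec) / length(pep_ch))
    colnames(exp_mat) <- pep_ch
    io_ch <- layout$interference_only_channels
    den_ch <- oil_denominator_channels(layout)
    oil_true <- ifelse(is_spike,
                       pmin(rowMeans(exp_mat[, io_ch, drop = FALSE]) /
                              rowMeans(exp_mat[, den_ch, drop = FALSE]), 1),
                       NA_real_)
    truth_list[[r]] <- data.frame(
      psm_id = psms$psm_id, raw_file = rf, species = psms$species_tag,
      protein_id = psms$protein_id, pep_class_true = class_lab,
      beta_precursor = as.numeric(beta_p),
      true_interference_frac = true_frac, oil_true = oil_true,
      outlier = outlier, y_precursor = y_prec, y_interference = y_int,
      y_total = y_exp, window_noise = window_noise,
      noise_estimate = noise_est, ppf_true = ppf, tiw_true = tiw,
      stringsAsFactors = FALSE)
    psm_list[[r]] <- psms
  }
  list(psms = do.call(rbind, psm_list),
       ms1 = ms1_runs,
       truth = do.call(rbind, truth_list),
       betas = list(precursor = cfg$beta_precursor,
                    nonprecursor = cfg$beta_nonprecursor,
                    noise = cfg$beta_noise),
       layout = layout)
}

#' Compare estimated against observed interference on simulated data
#'
#' Computes, for the spiked-proteome PSMs of a simulated dataset, the
#' Pearson correlations of the observed interference level (OIL) with the
#' estimated interference level (EIL) and with the isolation-window
#' impurity (1 - PPF), at PSM and at protein aggregation level, plus
#' per-group-pair median log2 fold changes of spiked proteins before and
#' after EIL-based interference correction, against the design values.
#'
#' @param metrics Metrics table (PSM table with `ppf` and reporter columns).
#' @param eil Numeric per-PSM EIL vector aligned with `metrics`.
#' @param truth Truth table from [simulate_dataset()].
#' @param layout A [channel_layout()].
#' @param eil_cap EIL ceiling for the correction step (default 0.8).
#' @return List with `correlations` (data frame: level, r_eil, r_impurity)
#'   and `fold_changes` (data frame: pair, design_log2fc, uncorrected and
#'   corrected median log2 fold change).
#' @export
evaluate_ground_truth <- function(metrics, eil, truth, layout, eil_cap = 0.8) {
  stopifnot(identical(metrics$psm_id, truth$psm_id))
  rep_mat <- reporter_matrix(metrics, layout)
  norm <- normalize_between_samples(rep_mat)$normalized
  spike <- truth$species == "spike"

  oil_psm <- as.numeric(compute_oil(norm[spike, , drop = FALSE], layout))
  imp <- 1 - metrics$ppf[spike]
  r_psm_eil <- stats::cor(eil[spike], oil_psm, use = "complete.obs")
  r_psm_imp <- stats::cor(imp, oil_psm, use = "complete.obs")

  w <- rowSums(norm[spike, , drop = FALSE], na.rm = TRUE)
  f <- factor(truth$protein_id[spike])
  agg_int <- rowsum(ifelse(is.na(norm[spike, , drop = FALSE]), 0,
                           norm[spike, , drop = FALSE]), f)
  wsum <- as.numeric(rowsum(w, f))
  agg_eil <- as.numeric(rowsum(w * eil[spike], f)) / wsum
  agg_imp <- as.numeric(rowsum(w * imp, f)) / wsum
  oil_prot <- as.numeric(compute_oil(agg_int, layout))
  r_prot_eil <- stats::cor(agg_eil, oil_prot, use = "complete.obs")
  r_prot_imp <- stats::cor(agg_imp, oil_prot, use = "complete.obs")

  corr <- correct_interference(norm, eil, layout, cap = eil_cap)$corrected
  fc <- design_fold_changes(layout)
  amounts <- vapply(layout$groups, `[[`, numeric(1), "amount")
  gchan <- lapply(layout$groups, `[[`, "channels")
  prot_fc <- function(mat, gnum, gden) {
    m <- rowsum(ifelse(is.na(mat[spike, , drop = FALSE]), 0,
                       mat[spike, , drop = FALSE]), f)
    num <- rowMeans(m[, gchan[[gnum]], drop = FALSE])
    den <- rowMeans(m[, gchan[[gden]], drop = FALSE])
    ok <- is.finite(num) & is.finite(den) & num > 0 & den > 0
    stats::median(log2(num[ok] / den[ok]))
  }
  fc$uncorrected_log2fc <- NA_real_
  fc$corrected_log2fc <- NA_real_
  for (i in seq_len(nrow(fc))) {
    fc$uncorrected_log2fc[i] <- prot_fc(norm, fc$numerator[i], fc$denominator[i])
    fc$corrected_log2fc[i] <- prot_fc(corr, fc$numerator[i], fc$denominator[i])
  }
  fc$design_log2fc <- log2(fc$fold_change)

  list(correlations = data.frame(
    level = c("psm", "protein"),
    r_eil = c(r_psm_eil, r_prot_eil),
    r_impurity = c(r_psm_imp, r_prot_imp)),
    fold_changes = fc)
}
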