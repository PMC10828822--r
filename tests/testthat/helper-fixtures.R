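# Small builders shared across tests; heavyweight simulated pipelines are
# cached so several tests can reuse one run.

tiny_layout <- function(nch = 4, tol_spacing = 1) {
  mz <- seq(126, by = tol_spacing, length.out = nch)
  names(mz) <- paste0("ch", seq_len(nch))
  channel_layout(names(mz), mz)
}

# an ms1_run from per-scan specs: list(scan=, rt=, mz=, int=, noise=)
make_run <- function(..., raw_file = "r1") {
  scans <- list(...)
  rows <- do.call(rbind, lapply(scans, function(s) {
    if (!length(s$mz))
      return(data.frame(raw_file = raw_file, scan_number = s$scan,
                        retention_time_min = s$rt, mz = NA_real_,
                        intensity = NA_real_, noise = NA_real_))
    data.frame(raw_file = raw_file, scan_number = s$scan,
               retention_time_min = s$rt, mz = s$mz, intensity = s$int,
               noise = if (is.null(s$noise)) rep(50, length(s$mz)) else s$noise)
  }))
  as_ms1_runs(rows)[[raw_file]]
}

make_psm <- function(ms2_scan = 2, precursor_mz = 500, rt = 10, charge = 2,
                     width = 2) {
  data.frame(ms2_scan = ms2_scan, precursor_mz = precursor_mz,
             retention_time_min = rt, charge = charge,
             isolation_width = width)
}

# small synthetic PSM table with reporter columns for a tiny layout
make_psm_table <- function(n = 3, layout = tiny_layout()) {
  d <- data.frame(
    raw_file = "r1", ms2_scan = seq_len(n) * 10L,
    sequence = rep(c("PEPTIDEK", "AGILVR", "HHARK"), length.out = n),
    modifications = "TMTpro (N-term)",
    charge = rep(2:3, length.out = n),
    precursor_mz = 500 + seq_len(n), retention_time_min = 10 + seq_len(n),
    tic = 1000 * seq_len(n), stringsAsFactors = FALSE)
  for (ch in layout$channel_names)
    d[[paste0("reporter_", ch)]] <- stats::runif(n, 10, 100)
  d
}

acc_cache <- new.env(parent = emptyenv())

# default study conditions: free interference draws
acc_default <- function() {
  if (is.null(acc_cache$default)) {
    cfg <- sim_config(seed = 1, psms_per_run = 5000)
    sim <- simulate_dataset(cfg)
    res <- suppressWarnings(suppressMessages(
      run_pipeline(sim$psms, sim$ms1, sim$layout)))
    acc_cache$default <- list(cfg = cfg, sim = sim, res = res)
  }
  acc_cache$default
}

# study conditions with the interference share centered on 0.3
acc_fixed <- function() {
  if (is.null(acc_cache$fixed)) {
    cfg <- sim_config(seed = 1, psms_per_run = 5000,
                      interference_fraction = 0.3)
    sim <- simulate_dataset(cfg)
    res <- suppressWarnings(suppressMessages(
      run_pipeline(sim$psms, sim$ms1, sim$layout)))
    acc_cache$fixed <- list(cfg = cfg, sim = sim, res = res)
  }
  acc_cache$fixed
}

# map fitted coefficient names onto the simulator's planted values; errors
# if a fitted class leaf mixes planted classes
planted_coef_vector <- function(fit, metrics, truth, betas) {
  out <- numeric(0)
  for (nm in names(fit$coef)) {
    fam <- fit$families[[nm]]
    if (fam == "noise") {
      out[nm] <- betas$noise
    } else if (fam == "nonprecursor") {
      ch <- sub("^nonprecursor.charge", "", nm)
      out[nm] <- betas$nonprecursor[[ch]]
    } else {
      lab <- sub("^precursor.class.", "", nm)
      b <- unique(truth$beta_precursor[metrics$pep_class == lab])
      if (length(b) != 1)
        stop("fitted class ", lab, " mixes planted classes")
      out[nm] <- b
    }
  }
  out
}
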