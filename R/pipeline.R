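#' Run the full interference-correction pipeline
#'
#' Drives the stages metrics -> density/noise -> classes -> fit -> EIL ->
#' normalize + correct (and, when site/protein groupings are supplied,
#' site-to-protein normalization) over in-memory inputs, optionally writing
#' stage outputs and a machine-readable run manifest to a directory. All
#' stages are deterministic; each is independently invocable through the
#' exported stage functions with identical results.
#'
#' @param psms PSM table (see [read_psm_table()]) or path to one.
#' @param ms1 Named list of `ms1_run` objects or path to an MS1 snapshot
#'   TSV.
#' @param layout A [channel_layout()] or path to a JSON layout.
#' @param out_dir Optional output directory; when given, stage TSVs, the
#'   fit JSON and `manifest.json` are written there.
#' @param min_leaf Class-tree leaf floor (default 100).
#' @param eil_cap EIL ceiling for correction (default 0.8).
#' @param gridsize Density grid nodes per axis (default 200).
#' @param site_grouping,protein_grouping Optional character vectors mapping
#'   PSMs to PTM-site / protein-group features (`NA` where a PSM belongs to
#'   neither); together with `site_protein_map` they trigger the
#'   site-normalization stage.
#' @param site_protein_map Data frame with columns `site_id`, `protein_id`
#'   linking site features to their parent protein groups.
#' @return List with `metrics` (PSM table with all derived columns
#'   including `pep_class` and `eil`), `tree`, `fits`, `normalized`,
#'   `corrected`, `factors`, optionally `site_ratios`, and `manifest`.
#' @export
run_pipeline <- function(psms, ms1, layout, out_dir = NULL,
                         min_leaf = 100, eil_cap = 0.8, gridsize = 200,
                         site_grouping = NULL, protein_grouping = NULL,
                         site_protein_map = NULL) {
  if (is.character(layout)) layout <- read_channel_layout(layout)
  if (is.character(psms)) psms <- read_psm_table(psms, layout)
  if (is.character(ms1)) ms1 <- read_ms1_snapshots(ms1)
  manifest <- list(package = "tmteil",
                   version = as.character(utils::packageVersion("tmteil")),
                   stages = list())
  stage <- function(name, n) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = name, rows = n)
    message(sprintf("[tmteil] stage %-12s rows=%d", name, n))
  }

  metrics <- compute_metrics(psms, ms1, layout)
  stage("metrics", nrow(metrics))

  dn <- add_noise_estimates(metrics, gridsize = gridsize)
  metrics <- dn$metrics
  stage("density", nrow(metrics))

  feats <- featurize_peptides(metrics)
  resp <- class_response(metrics)
  tree <- fit_class_tree(feats, resp, min_leaf = min_leaf)
  metrics$pep_class <- assign_class(tree, feats)
  stage("classes", nrow(class_tree_leaves(tree)))

  fit <- fit_interference_model(metrics, model = "general", layout = layout)
  metrics$eil <- fit$eil
  stage("fit", length(fit$fits))

  rep_mat <- reporter_matrix(metrics, layout)
  norm <- normalize_between_samples(rep_mat)
  corr <- correct_interference(norm$normalized, metrics$eil, layout,
                               cap = eil_cap)
  stage("correct", sum(!corr$skipped))

  out <- list(metrics = metrics, tree = tree, fits = fit$fits,
              normalized = norm$normalized, corrected = corr$corrected,
              factors = norm$factors)

  if (!is.null(site_grouping) && !is.null(protein_grouping) &&
      !is.null(site_protein_map)) {
    has_site <- !is.na(site_grouping)
    has_prot <- !is.na(protein_grouping)
    sites <- aggregate_features(corr$corrected[has_site, , drop = FALSE],
                                metrics$eil[has_site],
                                site_grouping[has_site])
    prots <- aggregate_features(corr$corrected[has_prot, , drop = FALSE],
                                metrics$eil[has_prot],
                                protein_grouping[has_prot])
    out$site_ratios <- normalize_sites(sites, prots, site_protein_map, layout)
    stage("normalize-sites",
          if (is.null(out$site_ratios)) 0L else nrow(out$site_ratios))
  }

  out$manifest <- manifest
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_psm_table(metrics, file.path(out_dir, "metrics.tsv"))
    write_fit_json(fit$fits, file.path(out_dir, "fit.json"))
    utils::write.table(cbind(psm_id = metrics$psm_id,
                             as.data.frame(corr$corrected)),
                       file.path(out_dir, "corrected.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
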