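## End-to-end orchestration: simulate (or read) -> OD-normalize -> plate
## correction -> phenotypes -> significance calls -> ESC clustering ->
## optional interaction network, with a manifest that makes reruns auditable.

#' Pipeline configuration
#'
#' @param dataset Label for the screen: `"KO"`, `"KOd"` or `"OE"`; selects
#'   the matching panel preset unless `panel` overrides it.
#' @param panel Optional [element_panel()] override.
#' @param alpha FDR level for significance calls.
#' @param min_frac Annealing consistency fraction.
#' @param min_cluster_size Minimum ESC cluster size.
#' @param correlation Edge-correlation estimator, `"pearson"` or
#'   `"spearman"`.
#' @param seed Master seed for any stochastic step.
#' @param input Either a `sim_config` (the screen is simulated) or the path
#'   to a plate CSV.
#' @param interactions Optional interaction data frame or BioGRID TAB path;
#'   enables the network stage.
#' @param out_dir Output directory; created if needed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(dataset = c("KO", "KOd", "OE"), panel = NULL,
                            alpha = 0.05, min_frac = 0.75,
                            min_cluster_size = 3,
                            correlation = c("pearson", "spearman"),
                            seed = 1L, input, interactions = NULL,
                            out_dir = tempfile("ionoscreen_run_")) {
  dataset <- match.arg(dataset)
  correlation <- match.arg(correlation)
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(panel)) {
    panel <- if (dataset == "OE") panel_oe() else panel_ko()
  }
  structure(list(dataset = dataset, panel = panel, alpha = alpha,
                 min_frac = min_frac, min_cluster_size = min_cluster_size,
                 correlation = correlation, seed = as.integer(seed),
                 input = input, interactions = interactions,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full screen-analysis pipeline
#'
#' Executes every stage in order, writes each stage's table under
#' `cfg$out_dir` and a `manifest.json` recording the configuration, seeds
#' and per-stage row counts. A rerun with identical configuration and
#' inputs writes byte-identical tables.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a results bundle: `raw`, `truth` (simulated runs
#'   only), `pheno`, `calls`, `clusters`, optional `network`, and
#'   `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (inherits(cfg$input, "sim_config")) {
    sim <- simulate_screen(cfg$input)
    raw <- sim$raw
    truth <- sim$truth
  } else {
    raw <- read_plate_table(cfg$input, cfg$panel)
  }

  odn <- od_normalize(raw)
  corr <- fit_plate_correction(odn)
  pheno <- summarize_phenotypes(odn, corr)
  calls <- call_significance(pheno, alpha = cfg$alpha, min_frac = cfg$min_frac)
  clusters <- esc_cluster(calls, min_size = cfg$min_cluster_size)
  clusters <- cluster_medians(clusters, calls)
  if (length(clusters$clusters) >= 2) {
    clusters <- hierarchical_order(clusters)
  }
  write_results(calls, clusters, file.path(cfg$out_dir, cfg$dataset))

  network <- NULL
  sig_genes <- names(calls$group)
  if (!is.null(cfg$interactions) && length(sig_genes) > 0) {
    inter <- if (is.character(cfg$interactions)) {
      read_biogrid_tab(cfg$interactions)
    } else cfg$interactions
    network <- build_subnetwork(sig_genes, inter, calls)
    network <- edge_correlations(network, calls, method = cfg$correlation)
    utils::write.csv(network$edges,
                     file.path(cfg$out_dir, paste0(cfg$dataset, "_edges.csv")),
                     row.names = FALSE, quote = FALSE)
  }

  manifest <- list(
    dataset = cfg$dataset,
    panel = as.character(cfg$panel),
    alpha = cfg$alpha,
    min_frac = cfg$min_frac,
    min_cluster_size = cfg$min_cluster_size,
    seed = cfg$seed,
    simulated = inherits(cfg$input, "sim_config"),
    counts = list(
      wells = nrow(raw$wells),
      genes = nrow(pheno$D),
      elements = length(cfg$panel),
      significant_calls = sum(calls$sign != 0),
      significant_genes = length(sig_genes),
      clustered = sum(vapply(clusters$clusters,
                             function(cl) length(cl$members), integer(1))),
      unclustered = length(clusters$unclustered),
      clusters = length(clusters$clusters),
      network_nodes = if (is.null(network)) NA else nrow(network$nodes),
      network_edges = if (is.null(network)) NA else nrow(network$edges)
    )
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(raw = raw, truth = truth, pheno = pheno, calls = calls,
                 clusters = clusters, network = network, manifest = manifest))
}
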