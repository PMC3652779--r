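## Interaction subnetworks. Given a gene set of interest (all genes
## significant for one element, or the members of selected clusters), the
## subnetwork keeps every known physical/genetic interaction with both
## endpoints inside the set; genes with no such edge are excluded from the
## node list (isolated genes are not shown).

#' Build an interaction subnetwork for a gene set
#'
#' @param geneset Character vector of tested genes.
#' @param interactions Data frame (`gene_a`, `gene_b`, `itype`) as returned
#'   by [read_biogrid_tab()] or [simulate_interaction_network()].
#' @param zt A `z_table`, `call_set` or `z_matrix` providing moderated-Z
#'   profiles; absent entries count as 0.
#' @param focal_element Optional element symbol: node direction/magnitude
#'   then refer to that element's Z; otherwise the element with the largest
#'   |Z| per gene is used.
#' @return A `subnetwork`: `nodes` data frame (gene_id, direction,
#'   magnitude), `edges` data frame (gene_a, gene_b, itype, r = NA until
#'   [edge_correlations()]), and `tested_genes`.
#' @export
build_subnetwork <- function(geneset, interactions, zt, focal_element = NULL) {
  stopifnot(length(geneset) > 0)
  Z <- if (is.matrix(zt)) zt else zt$Z
  geneset <- unique(geneset)
  e <- interactions[interactions$gene_a %in% geneset &
                      interactions$gene_b %in% geneset, , drop = FALSE]
  if (nrow(e) > 0) {
    key <- paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b), e$itype)
    e <- e[!duplicated(key), , drop = FALSE]
  }
  node_ids <- sort(unique(c(e$gene_a, e$gene_b)))
  dir <- mag <- rep(NA_real_, length(node_ids))
  for (i in seq_along(node_ids)) {
    g <- node_ids[i]
    prof <- if (g %in% rownames(Z)) Z[g, ] else rep(NA_real_, ncol(Z))
    prof[is.na(prof)] <- 0
    if (!is.null(focal_element)) {
      stopifnot(focal_element %in% colnames(Z))
      zi <- prof[[focal_element]]
    } else {
      zi <- prof[[which.max(abs(prof))]]
    }
    dir[i] <- sign(zi)
    mag[i] <- abs(zi)
  }
  e$r <- rep(NA_real_, nrow(e))
  structure(list(
    nodes = data.frame(gene_id = node_ids, direction = dir, magnitude = mag,
                       stringsAsFactors = FALSE),
    edges = e[, c("gene_a", "gene_b", "itype", "r"), drop = FALSE],
    tested_genes = geneset,
    focal_element = focal_element
  ), class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("subnetwork:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges (of",
      length(x$tested_genes), "tested genes)\n")
  invisible(x)
}

#' Annotate edges with ionomic profile correlations
#'
#' For each edge, the correlation of the two genes' moderated-Z vectors
#' across all panel elements. Entries absent from the Z table (blanked
#' sub-threshold cells of supplementary-style tables) are imputed as 0, the
#' null value of the moderated Z. Zero-variance profiles give an undefined
#' correlation; such edges are flagged with `r = NA`.
#'
#' @param subnetwork A `subnetwork`.
#' @param zt Z source as in [build_subnetwork()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return The `subnetwork` with the `r` edge column filled in.
#' @export
edge_correlations <- function(subnetwork, zt, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(subnetwork, "subnetwork"))
  Z <- if (is.matrix(zt)) zt else zt$Z
  prof <- function(g) {
    v <- if (g %in% rownames(Z)) as.numeric(Z[g, ]) else rep(0, ncol(Z))
    v[is.na(v)] <- 0
    v
  }
  e <- subnetwork$edges
  if (nrow(e) > 0) {
    for (i in seq_len(nrow(e))) {
      a <- prof(e$gene_a[i]); b <- prof(e$gene_b[i])
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        e$r[i] <- NA_real_
      } else {
        e$r[i] <- stats::cor(a, b, method = method)
      }
    }
  }
  subnetwork$edges <- e
  subnetwork
}

#' Network inclusion rate
#'
#' Percentage of the tested gene set that participates in at least one
#' physical or genetic interaction within the set:
#' 100 * |nodes| / |tested genes|.
#'
#' @param subnetwork A `subnetwork`.
#' @return Percentage in `[0, 100]`.
#' @export
inclusion_rate <- function(subnetwork) {
  stopifnot(inherits(subnetwork, "subnetwork"),
            length(subnetwork$tested_genes) > 0)
  100 * nrow(subnetwork$nodes) / length(subnetwork$tested_genes)
}

#' Network connectivity
#'
#' Edges divided by nodes. Typed duplicates (a pair interacting both
#' physically and genetically) count as separate edges, matching how the
#' per-type edge tallies are reported.
#'
#' @param subnetwork A `subnetwork`.
#' @return `|edges| / |nodes|`, or `NA` for an empty node set.
#' @export
connectivity <- function(subnetwork) {
  stopifnot(inherits(subnetwork, "subnetwork"))
  if (nrow(subnetwork$nodes) == 0) return(NA_real_)
  nrow(subnetwork$edges) / nrow(subnetwork$nodes)
}

#' Summary metrics of a subnetwork
#' @param subnetwork A `subnetwork`.
#' @return Named list: n_tested, n_nodes, n_edges_physical, n_edges_genetic,
#'   inclusion_rate, connectivity.
#' @export
subnetwork_metrics <- function(subnetwork) {
  list(
    n_tested = length(subnetwork$tested_genes),
    n_nodes = nrow(subnetwork$nodes),
    n_edges_physical = sum(subnetwork$edges$itype == "physical"),
    n_edges_genetic = sum(subnetwork$edges$itype == "genetic"),
    inclusion_rate = inclusion_rate(subnetwork),
    connectivity = connectivity(subnetwork)
  )
}
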