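## Exhaustive significance clustering (ESC): genes are partitioned by exact
## equality of their full per-element sign vectors. A panel of E elements
## admits 3^E patterns; observed patterns with fewer than min_size members
## are reported as unclustered.

pattern_key <- function(signs) {
  paste(c("-", "0", "+")[signs + 2L], collapse = "")
}

#' Cluster genes by identical significance pattern
#'
#' @param callset A `call_set`; only genes with at least one nonzero sign
#'   are eligible (others are rejected).
#' @param min_size Minimum members for a pattern to form a cluster
#'   (default 3); smaller patterns' genes are reported as unclustered.
#' @return A `cluster_set`: list of `clusters` (each with `pattern` key
#'   string, `signs` vector, `members`), `unclustered` gene ids, and the
#'   `panel`. Clusters are ordered by decreasing size, ties broken by
#'   pattern key.
#' @export
esc_cluster <- function(callset, min_size = 3) {
  stopifnot(inherits(callset, "call_set"))
  sgn <- callset$sign
  keep <- rowSums(sgn != 0) > 0
  sgn <- sgn[keep, , drop = FALSE]
  if (nrow(sgn) == 0) {
    return(structure(list(clusters = list(), unclustered = character(),
                          panel = callset$panel, row_order = integer(),
                          col_order = integer()),
                     class = "cluster_set"))
  }
  keys <- apply(sgn, 1, pattern_key)
  groups <- split(rownames(sgn), keys)
  sizes <- vapply(groups, length, integer(1))
  ord <- order(-sizes, names(groups))
  groups <- groups[ord]
  sizes <- sizes[ord]
  big <- sizes >= min_size
  clusters <- mapply(function(key, members) {
    list(pattern = key,
         signs = sgn[members[1], ],
         members = sort(members))
  }, names(groups)[big], groups[big], SIMPLIFY = FALSE, USE.NAMES = FALSE)
  names(clusters) <- sprintf("CLUSTER_%d", seq_along(clusters))
  unc <- unlist(groups[!big], use.names = FALSE)
  if (is.null(unc)) unc <- character(0)
  structure(list(clusters = clusters,
                 unclustered = sort(unc),
                 panel = callset$panel,
                 row_order = integer(), col_order = integer()),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "clusters,",
      length(x$unclustered), "unclustered genes\n")
  invisible(x)
}

#' Median moderated-Z profile of each cluster
#'
#' Per cluster and element, the median of member genes' moderated Z over all
#' panel elements (including non-significant ones, so sub-threshold medians
#' are visible in the heatmap).
#'
#' @param clusterset A `cluster_set`.
#' @param zt A `z_table` or `call_set` whose `Z` matrix covers all members.
#' @return The `cluster_set` with a `median_profiles` matrix
#'   (clusters x elements) attached, and each cluster carrying its profile.
#' @export
cluster_medians <- function(clusterset, zt) {
  stopifnot(inherits(clusterset, "cluster_set"))
  Z <- if (is.matrix(zt)) zt else zt$Z
  prof <- matrix(NA_real_, length(clusterset$clusters), length(clusterset$panel),
                 dimnames = list(names(clusterset$clusters),
                                 as.character(clusterset$panel)))
  for (i in seq_along(clusterset$clusters)) {
    members <- clusterset$clusters[[i]]$members
    missing <- setdiff(members, rownames(Z))
    if (length(missing) > 0) {
      stop("cluster member(s) missing from the Z table: ",
           paste(missing, collapse = ", "))
    }
    prof[i, ] <- apply(Z[members, as.character(clusterset$panel), drop = FALSE],
                       2, stats::median)
    clusterset$clusters[[i]]$median_profile <- prof[i, ]
  }
  clusterset$median_profiles <- prof
  clusterset
}

#' Hierarchical heatmap ordering of clusters and elements
#'
#' Complete-linkage agglomerative clustering on Euclidean distances, applied
#' to cluster median profiles (rows) and to elements across clusters
#' (columns). Deterministic given the input order.
#'
#' @param clusterset A `cluster_set` with `median_profiles`
#'   ([cluster_medians()]).
#' @return The `cluster_set` with `row_order` and `col_order` leaf
#'   permutations filled in (identity when fewer than 2 rows/columns).
#' @export
hierarchical_order <- function(clusterset) {
  stopifnot(inherits(clusterset, "cluster_set"),
            !is.null(clusterset$median_profiles))
  prof <- clusterset$median_profiles
  clusterset$row_order <- if (nrow(prof) < 2) seq_len(nrow(prof)) else
    stats::hclust(stats::dist(prof), method = "complete")$order
  clusterset$col_order <- if (ncol(prof) < 2) seq_len(ncol(prof)) else
    stats::hclust(stats::dist(t(prof)), method = "complete")$order
  clusterset
}

#' Export cluster median profiles as a banded heatmap table
#'
#' Rows and columns follow the hierarchical leaf orders; each cell carries a
#' band label relative to the dataset's significance cutoffs: `sig_neg`
#' (median below the negative cutoff), `neg` (negative but sub-threshold),
#' `pos` (in `[0, pos_cut)`, including 0) or `sig_pos`.
#'
#' @param clusterset A `cluster_set` with orders ([hierarchical_order()]).
#' @param thresholds `c(neg_cut, pos_cut)` with neg_cut < 0 < pos_cut, e.g.
#'   the cutoffs of a `call_set`.
#' @return Long data frame: cluster, size, element, median_z, band, in
#'   heatmap order.
#' @export
export_heatmap_table <- function(clusterset, thresholds) {
  stopifnot(inherits(clusterset, "cluster_set"),
            !is.null(clusterset$median_profiles),
            length(thresholds) == 2, thresholds[1] < 0, thresholds[2] > 0)
  prof <- clusterset$median_profiles
  ro <- if (length(clusterset$row_order)) clusterset$row_order else seq_len(nrow(prof))
  co <- if (length(clusterset$col_order)) clusterset$col_order else seq_len(ncol(prof))
  sizes <- vapply(clusterset$clusters, function(cl) length(cl$members),
                  integer(1))
  rows <- list()
  for (i in ro) {
    v <- prof[i, co]
    band <- ifelse(v < thresholds[1], "sig_neg",
                   ifelse(v < 0, "neg",
                          ifelse(v < thresholds[2], "pos", "sig_pos")))
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = rownames(prof)[i], size = unname(sizes[i]),
      element = colnames(prof)[co], median_z = as.numeric(v),
      band = unname(band), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## tabular views used by write_results()

cluster_membership <- function(clusterset) {
  rows <- lapply(names(clusterset$clusters), function(nm) {
    cl <- clusterset$clusters[[nm]]
    data.frame(gene_id = cl$members, cluster = nm, pattern = cl$pattern,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), cluster = character(),
               pattern = character(), stringsAsFactors = FALSE)
  if (length(clusterset$unclustered)) {
    out <- rbind(out, data.frame(gene_id = clusterset$unclustered,
                                 cluster = "unclustered", pattern = NA,
                                 stringsAsFactors = FALSE))
  }
  out
}

cluster_profile_table <- function(clusterset) {
  if (is.null(clusterset$median_profiles) ||
      nrow(clusterset$median_profiles) == 0) {
    return(data.frame(cluster = character(), pattern = character(),
                      size = integer(), stringsAsFactors = FALSE))
  }
  prof <- clusterset$median_profiles
  data.frame(
    cluster = rownames(prof),
    pattern = vapply(clusterset$clusters, function(cl) cl$pattern, character(1)),
    size = vapply(clusterset$clusters, function(cl) length(cl$members),
                  integer(1)),
    as.data.frame(prof),
    stringsAsFactors = FALSE, row.names = NULL)
}
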