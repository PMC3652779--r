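## Gene-set overlap and ontology enrichment. The overlap test is the exact
## upper-tail hypergeometric probability P(X >= k) of drawing k or more
## members of a K-gene set in n draws without replacement from a universe of
## N genes, summed in log space for numerical safety.

log_sum_exp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Hypergeometric gene-set overlap test
#'
#' @param N Universe size.
#' @param K Size of the reference set.
#' @param n Number of draws (size of the query set).
#' @param k Observed overlap.
#' @return An `overlap_test` list: N, K, n, k and `p_value` = P(X >= k).
#' @examples
#' hypergeom_overlap(N = 10, K = 4, n = 5, k = 3)$p_value
#' @export
hypergeom_overlap <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, n >= 0, k >= 0, K <= N, n <= N)
  if (k > min(K, n)) stop("overlap k exceeds min(K, n)")
  if (k == 0) {
    p <- 1
  } else {
    j <- k:min(K, n)
    p <- min(1, exp(log_sum_exp(stats::dhyper(j, K, N - K, n, log = TRUE))))
  }
  structure(list(N = N, K = K, n = n, k = k, p_value = p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("hypergeometric overlap: k=%g of n=%g vs K=%g in N=%g, P(X>=k) = %.6g\n",
              x$k, x$n, x$K, x$N, x$p_value))
  invisible(x)
}

#' Build an ontology DAG with propagated annotations
#'
#' Combines a parsed OBO ontology ([read_obo()]) with gene-to-term
#' annotations ([read_gaf()] or any gene/term data frame) and propagates
#' each gene's annotations to all ancestor terms over is_a/part_of edges.
#'
#' @param obo List from [read_obo()] (or a compatible `terms`/`parents`
#'   list).
#' @param annotations Data frame with columns `gene` and `term`.
#' @param namespace Optional namespace filter (`"biological_process"` etc.).
#' @return An `ontology_dag`: `terms`, `parents`, `children`,
#'   `annotations` (term -> gene vector, ancestry-closed) and a topological
#'   order `topo` with children before parents.
#' @export
ontology_dag <- function(obo, annotations, namespace = NULL) {
  terms <- obo$terms
  if (!is.null(namespace)) {
    terms <- terms[terms$namespace == namespace, , drop = FALSE]
  }
  ids <- terms$id
  parents <- lapply(obo$parents[ids], function(p) intersect(p, ids))
  names(parents) <- ids

  # Kahn topological sort; a term is emitted once all its children are done,
  # so the order lists children before parents. Detects cycles.
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  remaining <- stats::setNames(vapply(children, length, integer(1)), ids)
  queue <- ids[remaining == 0]
  topo <- character(0)
  while (length(queue) > 0) {
    t <- queue[1]; queue <- queue[-1]
    topo <- c(topo, t)
    for (p in parents[[t]]) {
      remaining[p] <- remaining[p] - 1L
      if (remaining[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(topo) != length(ids)) stop("ontology contains a cycle")

  ann <- annotations[annotations$term %in% ids, , drop = FALSE]
  direct <- lapply(split(ann$gene, ann$term), unique)
  prop <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) prop[[id]] <- direct[[id]]
  for (t in topo) {                                  # children first: push up
    for (p in parents[[t]]) prop[[p]] <- union(prop[[p]], prop[[t]])
  }
  prop <- lapply(prop, function(g) if (is.null(g)) character() else sort(g))
  structure(list(terms = terms, parents = parents, children = children,
                 annotations = prop, topo = topo),
            class = "ontology_dag")
}

dag_descendants <- function(dag, term) {
  out <- character(0)
  frontier <- dag$children[[term]]
  while (length(frontier) > 0) {
    out <- union(out, frontier)
    frontier <- unique(unlist(dag$children[frontier], use.names = FALSE))
    frontier <- setdiff(frontier, out)
  }
  out
}

#' Conditional hypergeometric ontology enrichment
#'
#' Terms are tested children before parents. When a parent is tested, genes
#' annotated to any of its already-significant (p <= alpha_cond)
#' descendants are removed from the term's gene set and from the universe
#' counts for that test, so a parent cannot appear enriched merely because a
#' specific child is. With no significant children the conditional test
#' equals the plain hypergeometric test.
#'
#' @param geneset Character vector, a subset of `universe`.
#' @param universe Character vector of all tested genes.
#' @param dag An [ontology_dag()].
#' @param alpha_cond Significance threshold used for conditioning
#'   (default 0.05).
#' @param min_genes Minimum geneset genes annotated to a term for it to be
#'   tested (default 2).
#' @return Data frame term/name/k/K/n/N/p_value, sorted by p-value.
#' @export
conditional_hypergeom_go <- function(geneset, universe, dag,
                                     alpha_cond = 0.05, min_genes = 2) {
  stopifnot(inherits(dag, "ontology_dag"))
  missing <- setdiff(geneset, universe)
  if (length(missing) > 0) {
    stop("geneset gene(s) absent from universe: ",
         paste(missing, collapse = ", "))
  }
  geneset <- unique(geneset); universe <- unique(universe)
  sig <- character(0)
  rows <- list()
  pvals <- stats::setNames(rep(NA_real_, length(dag$topo)), dag$topo)
  for (t in dag$topo) {
    ann_t <- intersect(dag$annotations[[t]], universe)
    if (length(intersect(ann_t, geneset)) < min_genes) next
    desc_sig <- intersect(dag_descendants(dag, t), sig)
    excl <- intersect(
      unique(unlist(dag$annotations[desc_sig], use.names = FALSE)), universe)
    uni_c <- setdiff(universe, excl)
    gs_c <- setdiff(geneset, excl)
    ann_c <- setdiff(ann_t, excl)
    k <- length(intersect(ann_c, gs_c))
    K <- length(ann_c)
    n <- length(gs_c)
    N <- length(uni_c)
    p <- if (K == 0 || n == 0) 1 else hypergeom_overlap(N, K, n, k)$p_value
    pvals[t] <- p
    if (p <= alpha_cond) sig <- c(sig, t)
    rows[[length(rows) + 1L]] <- data.frame(
      term = t,
      name = dag$terms$name[match(t, dag$terms$id)],
      k = k, K = K, n = n, N = N, p_value = p,
      conditioned_on = length(desc_sig),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(), name = character(), k = integer(),
               K = integer(), n = integer(), N = integer(),
               p_value = numeric(), conditioned_on = integer(),
               stringsAsFactors = FALSE)
  out[order(out$p_value, out$term), , drop = FALSE]
}
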