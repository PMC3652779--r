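# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (sorting, enumeration, dictionaries) so they never share code with the
# implementation paths they check.

# Build a phenotype_table directly from a replicate-value array
# (genes x elements x replicates), bypassing the plate machinery.
pheno_from_reps <- function(reps, panel = NULL) {
  genes <- dimnames(reps)[[1]]
  els <- dimnames(reps)[[2]]
  if (is.null(panel)) panel <- element_panel(els)
  D <- apply(reps, c(1, 2), mean)
  S <- apply(reps, c(1, 2), sd)
  N <- matrix(dim(reps)[3], length(genes), length(els),
              dimnames = list(genes, els))
  long <- do.call(rbind, lapply(seq_along(els), function(j) {
    do.call(rbind, lapply(seq_along(genes), function(i) {
      data.frame(gene_id = genes[i], element = els[j],
                 replicate = seq_len(dim(reps)[3]),
                 value = reps[i, j, ], stringsAsFactors = FALSE)
    }))
  }))
  structure(list(D = D, sigma_tilde = S, n_reps = N,
                 replicate_values = long, flagged = character(),
                 flagged_single = character(), panel = panel),
            class = "phenotype_table")
}

# Phenotype table from a D matrix alone (replicates synthesized as exact
# copies; only useful for operations that ignore replicate spread).
pheno_from_D <- function(D, sigma = NULL) {
  if (is.null(sigma)) sigma <- matrix(1, nrow(D), ncol(D), dimnames = dimnames(D))
  reps <- array(rep(D, 4), dim = c(nrow(D), ncol(D), 4),
                dimnames = c(dimnames(D), list(NULL)))
  p <- pheno_from_reps(reps)
  p$D <- D
  p$sigma_tilde <- sigma
  p
}

# Minimal call_set around a sign matrix (for clustering tests).
call_set_from_sign <- function(sgn, Z = NULL) {
  if (is.null(Z)) Z <- sgn * 5
  structure(list(Z = Z, q = abs(sgn) * 0.01 + (sgn == 0) * 0.99,
                 sign = sgn, perCh = sgn * 0.3,
                 annealing_pass = sgn != 0,
                 group = setNames(rep("B", sum(rowSums(sgn != 0) > 0)),
                                  rownames(sgn)[rowSums(sgn != 0) > 0]),
                 cutoffs = c(neg_cut = -3, pos_cut = 3), alpha = 0.05,
                 panel = element_panel(colnames(sgn))),
            class = "call_set")
}

# A 24-column BioGRID TAB 2.0 line.
biogrid_line <- function(sys_a, sys_b, type = "physical",
                         sym_a = sys_a, sym_b = sys_b, org = "559292") {
  paste(c("1", "100", "101", "200", "201", sys_a, sys_b, sym_a, sym_b,
          "-", "-", "Two-hybrid", type, "Author (2010)", "12345",
          org, org, "Low Throughput", "-", "-", "-", "-", "-", "BIOGRID"),
        collapse = "\t")
}

## ---- independent oracles ----

# Benjamini-Hochberg by explicit sort-and-step.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  if (n > 1) for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Upper-tail hypergeometric by exhaustive enumeration with choose().
hyper_tail_oracle <- function(N, K, n, k) {
  if (k == 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Complete-linkage agglomeration by brute force; returns sorted merge heights.
complete_linkage_heights <- function(X) {
  clusters <- as.list(seq_len(nrow(X)))
  d <- as.matrix(dist(X))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Dictionary-based grouping of identical sign rows.
esc_oracle <- function(sgn, min_size) {
  keys <- apply(sgn, 1, paste, collapse = ",")
  groups <- split(rownames(sgn), keys)
  unc <- unlist(Filter(function(g) length(g) < min_size, groups),
                use.names = FALSE)
  list(clustered = lapply(Filter(function(g) length(g) >= min_size, groups), sort),
       unclustered = if (is.null(unc)) character(0) else sort(unc))
}
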