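## Robust significance testing. The moderated Z statistic standardizes each
## gene's phenotype against the across-gene median, scaled by the median
## absolute deviation times 1.4826 (the factor that makes the MAD an unbiased
## estimate of the standard deviation under normality):
##
##   Z_ge = (D_ge - median_g D_ge) / (1.4826 * median_g |D_ge - median_g D_ge|)

#' Moderated Z statistics per gene and element
#'
#' Medians are taken across genes within one element. Genes flagged as
#' single-replicate by [summarize_phenotypes()] are excluded. If an element's
#' MAD across genes is zero its Z values are undefined (NA) and a warning is
#' emitted.
#'
#' @param pheno A `phenotype_table`.
#' @return A `z_table`: list with matrix `Z` (genes x elements), the `panel`
#'   and a pointer-free copy of the inputs needed downstream.
#' @export
moderated_z <- function(pheno) {
  stopifnot(inherits(pheno, "phenotype_table"))
  D <- pheno$D
  drop <- rownames(D) %in% pheno$flagged_single
  D <- D[!drop, , drop = FALSE]
  if (nrow(D) < 3) stop("need at least 3 genes per element")
  Z <- D
  for (j in seq_len(ncol(D))) {
    x <- D[, j]
    med <- stats::median(x, na.rm = TRUE)
    mad_ <- stats::median(abs(x - med), na.rm = TRUE)
    if (!is.finite(mad_) || mad_ == 0) {
      warning("MAD across genes is 0 for element ", colnames(D)[j],
              "; Z undefined")
      Z[, j] <- NA_real_
    } else {
      Z[, j] <- (x - med) / (1.4826 * mad_)
    }
  }
  structure(list(Z = Z, panel = pheno$panel, alpha = NA_real_,
                 q = NULL, p = NULL, cutoffs = NULL),
            class = "z_table")
}

#' @export
print.z_table <- function(x, ...) {
  cat("z_table:", nrow(x$Z), "genes x", ncol(x$Z), "elements")
  if (!is.null(x$q)) {
    cat("; FDR", x$alpha, "cutoffs (", round(x$cutoffs[1], 3), ",",
        round(x$cutoffs[2], 3), ")")
  }
  cat("\n")
  invisible(x)
}

#' Convert moderated Z to q-values and per-direction cutoffs
#'
#' Two-sided standard-normal p-values 2 * pnorm(-|Z|) are adjusted by
#' Benjamini-Hochberg jointly over all gene x element cells of the dataset
#' (one cutoff pair per dataset, not per element). The reported cutoffs are
#' the extreme observed significant Z per direction: `neg_cut` is the
#' largest (closest to zero) significant negative Z and `pos_cut` the
#' smallest significant positive Z, hence slightly asymmetric. With no
#' significant calls on a side the sentinel -Inf/+Inf is reported.
#'
#' @param zt A `z_table` from [moderated_z()].
#' @param alpha FDR level, default 0.05.
#' @return The `z_table` with `p`, `q`, `alpha` and `cutoffs = c(neg, pos)`
#'   filled in.
#' @export
z_to_q <- function(zt, alpha = 0.05) {
  stopifnot(inherits(zt, "z_table"), alpha > 0, alpha < 1)
  Z <- zt$Z
  p <- 2 * stats::pnorm(-abs(Z))
  q <- p
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  sig <- ok & q <= alpha
  neg <- Z[sig & Z < 0]
  pos <- Z[sig & Z > 0]
  zt$p <- p
  zt$q <- q
  zt$alpha <- alpha
  zt$cutoffs <- c(neg_cut = if (length(neg)) max(neg) else -Inf,
                  pos_cut = if (length(pos)) min(pos) else Inf)
  zt
}

#' Replicate-consistency (annealing) filter
#'
#' A candidate significant call for gene g and element e passes only if at
#' least 75% of g's biological replicates deviate from the element's median
#' in the direction of the call, by at least twice the median absolute
#' deviation. The reference median and MAD are computed on replicate-level
#' values pooled across all genes for that element (raw MAD, no 1.4826
#' factor).
#'
#' @param pheno A `phenotype_table` (provides replicate values).
#' @param zt A `z_table` (provides the call directions).
#' @param min_frac Required fraction of consistent replicates, default 0.75
#'   (inclusive).
#' @return Logical matrix (genes x elements); NA where Z is undefined.
#' @export
annealing_filter <- function(pheno, zt, min_frac = 0.75) {
  stopifnot(inherits(pheno, "phenotype_table"), inherits(zt, "z_table"))
  Z <- zt$Z
  pass <- matrix(NA, nrow(Z), ncol(Z), dimnames = dimnames(Z))
  rv <- pheno$replicate_values
  for (el in colnames(Z)) {
    xe <- rv[rv$element == el, , drop = FALSE]
    m_e <- stats::median(xe$value)
    mad_e <- stats::median(abs(xe$value - m_e))
    by_gene <- split(xe$value, xe$gene_id)
    for (g in rownames(Z)) {
      z <- Z[g, el]
      if (is.na(z)) next
      x <- by_gene[[g]]
      if (is.null(x)) next
      dir_ok <- sign(x - m_e) == sign(z)
      mag_ok <- abs(x - m_e) >= 2 * mad_e
      pass[g, el] <- mean(dir_ok & mag_ok) >= min_frac
    }
  }
  pass
}

#' Percent change effect size
#'
#' perCh_ge = (s_ge - mean_g s_ge) / mean_g s_ge with s_ge =
#' sigma_tilde_ge * D_ge, means taken across genes within an element. A
#' value of 0.9 denotes a +90% change relative to the across-mutant mean.
#'
#' @param pheno A `phenotype_table`.
#' @return Numeric matrix (genes x elements); columns whose across-gene mean
#'   is zero are NA with a warning.
#' @export
percent_change <- function(pheno) {
  stopifnot(inherits(pheno, "phenotype_table"))
  s <- pheno$sigma_tilde * pheno$D
  out <- s
  for (j in seq_len(ncol(s))) {
    m <- mean(s[, j], na.rm = TRUE)
    if (!is.finite(m) || m == 0) {
      warning("zero across-gene mean for element ", colnames(s)[j],
              "; perCh undefined")
      out[, j] <- NA_real_
    } else {
      out[, j] <- (s[, j] - m) / m
    }
  }
  out
}

#' Assign A/B/C effect-size groups
#'
#' Over a gene's significant elements the most extreme perCh decides the
#' group: C for a >= 100% increase or <= -50% decrease, B for a 20-100%
#' increase or -20 to -50% decrease, A for changes within +/-20%. Band
#' boundaries are inclusive toward the more extreme group.
#'
#' @param perCh Matrix from [percent_change()].
#' @param sign_mat Sign matrix in \{-1, 0, +1\} from
#'   [significance_pattern()].
#' @return Named character vector of groups for genes with at least one
#'   significant element.
#' @export
assign_groups <- function(perCh, sign_mat) {
  stopifnot(identical(dim(perCh), dim(sign_mat)))
  genes <- rownames(sign_mat)[rowSums(sign_mat != 0, na.rm = TRUE) > 0]
  grp <- stats::setNames(character(length(genes)), genes)
  for (g in genes) {
    pc <- perCh[g, sign_mat[g, ] != 0 & !is.na(sign_mat[g, ])]
    pc <- pc[!is.na(pc)]
    grp[g] <- if (any(pc >= 1.0 | pc <= -0.5)) "C"
    else if (any(pc >= 0.2 | pc <= -0.2)) "B"
    else "A"
  }
  grp
}

#' Significance sign pattern
#'
#' sign = +1 where q <= alpha, Z > 0 and the annealing filter passed; -1
#' symmetrically; 0 otherwise (including undefined cells).
#'
#' @param zt A `z_table` with q-values ([z_to_q()]).
#' @param annealing_pass Logical matrix from [annealing_filter()].
#' @return Integer matrix in \{-1, 0, +1\}.
#' @export
significance_pattern <- function(zt, annealing_pass) {
  stopifnot(inherits(zt, "z_table"), !is.null(zt$q))
  Z <- zt$Z
  sgn <- matrix(0L, nrow(Z), ncol(Z), dimnames = dimnames(Z))
  ok <- !is.na(Z) & !is.na(zt$q) & zt$q <= zt$alpha &
    !is.na(annealing_pass) & annealing_pass
  sgn[ok & Z > 0] <- 1L
  sgn[ok & Z < 0] <- -1L
  sgn
}

#' Run the complete significance stage
#'
#' Convenience wrapper: moderated Z, BH q-values, annealing filter, percent
#' change, sign pattern and effect groups in one call.
#'
#' @param pheno A `phenotype_table`.
#' @param alpha FDR level, default 0.05.
#' @param min_frac Annealing consistency fraction, default 0.75.
#' @return A `call_set`: list with matrices `Z`, `q`, `sign`, `perCh`,
#'   `annealing_pass`, vector `group`, the `cutoffs` and `alpha`.
#' @export
call_significance <- function(pheno, alpha = 0.05, min_frac = 0.75) {
  zt <- z_to_q(moderated_z(pheno), alpha = alpha)
  ann <- annealing_filter(pheno, zt, min_frac = min_frac)
  sgn <- significance_pattern(zt, ann)
  perCh <- percent_change(pheno)[rownames(zt$Z), , drop = FALSE]
  grp <- assign_groups(perCh, sgn)
  structure(list(Z = zt$Z, q = zt$q, sign = sgn, perCh = perCh,
                 annealing_pass = ann, group = grp,
                 cutoffs = zt$cutoffs, alpha = alpha, panel = pheno$panel),
            class = "call_set")
}

#' @export
print.call_set <- function(x, ...) {
  cat("call_set:", sum(x$sign != 0), "significant calls across",
      length(x$group), "genes (FDR", x$alpha, ")\n")
  invisible(x)
}
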