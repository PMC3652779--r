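## Control-based normalization. Corrections are estimated per element on the
## log scale from control wells only: instrument-day effects are fit as fixed
## offsets and plate-within-day effects are shrunken toward 0 by an
## empirical-Bayes factor (a surrogate for a full mixed-model fit, which the
## published normalization delegates to external software).

#' Normalize concentrations to culture optical density
#'
#' Divides every element concentration by the well's OD600, putting wells
#' with different culture densities on a per-biomass scale.
#'
#' @param raw A `raw_screen_set`.
#' @return A `raw_screen_set` with concentrations replaced by conc/od600.
#' @export
od_normalize <- function(raw) {
  stopifnot(inherits(raw, "raw_screen_set"))
  bad <- raw$wells$od600 <= 0
  if (any(bad)) {
    stop("od600 must be > 0; offending well(s): ",
         paste(utils::head(paste0(raw$wells$plate_id[bad], ":",
                                  raw$wells$well[bad]), 5), collapse = ", "))
  }
  for (el in as.character(raw$panel)) {
    raw$wells[[el]] <- raw$wells[[el]] / raw$wells$od600
  }
  raw
}

#' Estimate per-plate log-scale corrections from control wells
#'
#' For each element independently, control-well log concentrations are
#' decomposed into a grand mean, fixed day offsets, and plate-within-day
#' residual means. The plate residuals are shrunken toward zero by the
#' empirical-Bayes factor lambda = s2_plate / (s2_plate + s2_within / n_c),
#' where s2_within is the pooled within-plate control variance, s2_plate the
#' method-of-moments between-plate variance component, and n_c the number of
#' control wells on the plate. The returned correction for a plate is
#' (day offset + shrunken plate residual); subtracting it from log values
#' centers technical variation while leaving the grand mean intact.
#'
#' @param raw_odnorm An OD-normalized `raw_screen_set`.
#' @return A `plate_correction`: data frame (plate_id, run_id, element,
#'   correction) with the panel attached.
#' @export
fit_plate_correction <- function(raw_odnorm) {
  stopifnot(inherits(raw_odnorm, "raw_screen_set"))
  w <- raw_odnorm$wells
  plates <- unique(w[, c("plate_id", "run_id")])
  has_ctrl <- tapply(w$role == "control", w$plate_id, any)
  if (!all(plates$plate_id %in% names(has_ctrl)[has_ctrl])) {
    missing <- setdiff(plates$plate_id, names(has_ctrl)[has_ctrl])
    stop("plate(s) without control wells: ", paste(missing, collapse = ", "))
  }
  ctrl <- w[w$role == "control", , drop = FALSE]
  out <- vector("list", length(raw_odnorm$panel))
  for (j in seq_along(raw_odnorm$panel)) {
    el <- as.character(raw_odnorm$panel)[j]
    x <- log(ctrl[[el]])
    if (any(!is.finite(x))) stop("non-positive control concentration for ", el)
    if (stats::var(x) == 0 || length(x) < 2) {
      warning("zero variance among controls for element ", el,
              "; correction set to 0")
      out[[j]] <- data.frame(plate_id = plates$plate_id, run_id = plates$run_id,
                             element = el, correction = 0,
                             stringsAsFactors = FALSE)
      next
    }
    grand <- mean(x)
    day_mean <- tapply(x, ctrl$run_id, mean)
    day_off <- day_mean - grand
    plate_mean <- tapply(x, ctrl$plate_id, mean)
    n_per_plate <- tapply(x, ctrl$plate_id, length)
    resid_plate <- plate_mean - grand - day_off[plates$run_id[
      match(names(plate_mean), plates$plate_id)]]

    # variance components: pooled within-plate vs between-plate (moments)
    within_ss <- tapply(x, ctrl$plate_id, function(v) sum((v - mean(v))^2))
    df_within <- sum(n_per_plate - 1)
    s2_within <- if (df_within > 0) sum(within_ss) / df_within else 0
    nbar <- mean(n_per_plate)
    s2_plate_raw <- stats::var(as.numeric(resid_plate)) - s2_within / nbar
    s2_plate <- max(0, s2_plate_raw, na.rm = TRUE)
    lambda <- if (s2_plate == 0 && s2_within == 0) 1 else
      s2_plate / (s2_plate + s2_within / nbar)

    corr <- day_off[plates$run_id] + lambda * resid_plate[plates$plate_id]
    out[[j]] <- data.frame(plate_id = plates$plate_id, run_id = plates$run_id,
                           element = el, correction = as.numeric(corr),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, panel = raw_odnorm$panel, class = c("plate_correction",
                                                     class(res)))
}

#' Apply plate corrections to a raw screen set
#'
#' Each concentration is divided by exp(correction) for its plate and
#' element, i.e. the additive log correction is removed and values returned
#' on the measurement scale.
#'
#' @param raw_odnorm OD-normalized `raw_screen_set`.
#' @param correction A `plate_correction` from [fit_plate_correction()].
#' @return Corrected `raw_screen_set`.
#' @export
apply_plate_correction <- function(raw_odnorm, correction) {
  stopifnot(inherits(raw_odnorm, "raw_screen_set"),
            inherits(correction, "plate_correction"))
  w <- raw_odnorm$wells
  if (!all(w$plate_id %in% correction$plate_id)) {
    stop("correction does not cover plate(s): ",
         paste(setdiff(w$plate_id, correction$plate_id), collapse = ", "))
  }
  for (el in as.character(raw_odnorm$panel)) {
    ce <- correction[correction$element == el, , drop = FALSE]
    fac <- exp(ce$correction[match(w$plate_id, ce$plate_id)])
    w[[el]] <- w[[el]] / fac
  }
  raw_odnorm$wells <- w
  raw_odnorm
}

#' Summarize corrected replicate wells into gene x element phenotypes
#'
#' For each mutant strain (gene) and element, the plate-corrected replicate
#' values are collected; the phenotype D is their mean and sigma_tilde their
#' sample standard deviation (n - 1 denominator). Genes observed in fewer
#' than two replicate wells cannot provide a scale estimate and are flagged
#' for exclusion from significance testing.
#'
#' @param raw_odnorm OD-normalized `raw_screen_set`.
#' @param correction A `plate_correction`; corrections must cover all plates.
#' @return A `phenotype_table`: list with matrices `D`, `sigma_tilde`,
#'   `n_reps` (genes x elements), long data frame `replicate_values`
#'   (gene_id, element, replicate, value), `flagged` gene ids (single
#'   replicate or zero scale) and the `panel`.
#' @export
summarize_phenotypes <- function(raw_odnorm, correction) {
  corrected <- apply_plate_correction(raw_odnorm, correction)
  w <- corrected$wells[corrected$wells$role == "mutant", , drop = FALSE]
  els <- as.character(corrected$panel)
  genes <- sort(unique(w$strain_id))
  gi <- match(w$strain_id, genes)

  D <- matrix(NA_real_, length(genes), length(els),
              dimnames = list(genes, els))
  S <- D
  N <- matrix(0L, length(genes), length(els), dimnames = list(genes, els))
  reps <- vector("list", length(els))
  for (j in seq_along(els)) {
    v <- w[[els[j]]]
    D[, j] <- as.numeric(tapply(v, gi, mean)[as.character(seq_along(genes))])
    S[, j] <- as.numeric(tapply(v, gi, stats::sd)[as.character(seq_along(genes))])
    N[, j] <- as.integer(tapply(v, gi, length)[as.character(seq_along(genes))])
    reps[[j]] <- data.frame(gene_id = w$strain_id, element = els[j],
                            replicate = w$replicate, value = v,
                            stringsAsFactors = FALSE)
  }
  replicate_values <- do.call(rbind, reps)
  single <- genes[apply(N, 1, min) < 2L]
  zero_scale <- genes[apply(S, 1, function(s) any(!is.na(s) & s == 0))]
  structure(list(D = D, sigma_tilde = S, n_reps = N,
                 replicate_values = replicate_values,
                 flagged = union(single, zero_scale),
                 flagged_single = single,
                 panel = corrected$panel),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat("phenotype_table:", nrow(x$D), "genes x", ncol(x$D), "elements;",
      length(x$flagged), "flagged\n")
  invisible(x)
}
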