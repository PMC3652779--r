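## Plate-screen simulator with known ground truth. The generative model is
## log-normal: multiplicative gene, spike, day, plate and replicate effects on
## a per-element baseline concentration, times the well's optical density
## (element content scales with biomass, so OD normalization is non-trivial).

# Typical solution concentrations (ppm) seen in digested yeast screens; used
# as per-element baselines when the caller does not supply them.
DEFAULT_BASELINE_PPM <- c(
  Ca = 1.5, Cd = 0.005, Co = 0.01, Cu = 0.03, Fe = 0.5, K = 80, Mg = 10,
  Mn = 0.05, Mo = 0.01, Na = 5, Ni = 0.01, P = 100, S = 30, Zn = 0.5,
  As = 0.005, Cl = 2, Se = 0.005
)

# Deterministic stream-splitting: each stochastic stage of the simulator uses
# seed_stream(master, k) for a distinct small k, so stages can be re-drawn in
# isolation. Kept below 2^31 - 1 (R integer range).
seed_stream <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)
}

#' Configuration for the plate-screen simulator
#'
#' Defaults mirror the screening layout of the study system: 96-well plates
#' carrying four fixed control strains plus up to 20 mutant strains, three
#' plates per instrument day, and 4, 8 or 16 biological replicates per
#' strain. Dispersion defaults are realistic screen values: ~10% replicate
#' CV and ~5% plate/day effects and gene baseline heterogeneity, all on the
#' log scale.
#'
#' @param n_genes Number of mutant strains (genes) to simulate.
#' @param n_controls_per_plate Control wells per plate (fixed strain ids
#'   shared across all plates). Default 4.
#' @param mutants_per_plate Mutant wells per plate, at most 20.
#' @param plates_per_day Plates analyzed per instrument day. Default 3.
#' @param replicates Biological replicates per strain: 4, 8 or 16.
#' @param panel An [element_panel()].
#' @param baseline_log_mean,baseline_log_sd Named per-element log-scale
#'   baseline mean concentration (ppm) and gene-to-gene baseline SD.
#' @param plate_effect_sd,day_effect_sd,replicate_noise_sd Log-scale SDs of
#'   the multiplicative plate, day and replicate effects.
#' @param od_mean,od_sd Median OD600 and its log-scale SD.
#' @param spike_fraction Probability that a given gene x element carries a
#'   true perturbation.
#' @param spike_effect_range Fold-change range `c(lo, hi)` with `lo > 1`;
#'   each spike is drawn log-uniformly in the range with a random sign, so
#'   effects never approach 1.
#' @param seed Master seed; all draws derive from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes,
                       n_controls_per_plate = 4,
                       mutants_per_plate = 20,
                       plates_per_day = 3,
                       replicates = 4,
                       panel = panel_ko(),
                       baseline_log_mean = NULL,
                       baseline_log_sd = NULL,
                       plate_effect_sd = 0.05,
                       day_effect_sd = 0.05,
                       replicate_noise_sd = 0.10,
                       od_mean = 1.0,
                       od_sd = 0.15,
                       spike_fraction = 0.02,
                       spike_effect_range = c(2, 4),
                       seed = 1L) {
  stopifnot(inherits(panel, "element_panel"))
  if (mutants_per_plate > 20) {
    stop("mutants_per_plate must be <= 20 (screen layout caps mutant wells at 20)")
  }
  if (n_controls_per_plate + mutants_per_plate > 96) {
    stop("controls + mutants exceed the 96-well grid")
  }
  if (!replicates %in% c(4L, 8L, 16L)) {
    stop("replicates must be 4, 8 or 16")
  }
  if (any(c(plate_effect_sd, day_effect_sd, replicate_noise_sd, od_sd) < 0)) {
    stop("standard deviations must be >= 0")
  }
  if (spike_fraction < 0 || spike_fraction > 1) stop("spike_fraction in [0,1]")
  if (length(spike_effect_range) != 2 || spike_effect_range[1] <= 1 ||
      spike_effect_range[2] < spike_effect_range[1]) {
    stop("spike_effect_range must be c(lo, hi) with 1 < lo <= hi")
  }
  els <- as.character(panel)
  if (is.null(baseline_log_mean)) {
    ppm <- DEFAULT_BASELINE_PPM[els]
    ppm[is.na(ppm)] <- 1
    baseline_log_mean <- stats::setNames(log(as.numeric(ppm)), els)
  }
  if (is.null(baseline_log_sd)) {
    baseline_log_sd <- stats::setNames(rep(0.05, length(els)), els)
  }
  stopifnot(all(els %in% names(baseline_log_mean)),
            all(els %in% names(baseline_log_sd)),
            all(baseline_log_sd[els] >= 0))
  structure(list(
    n_genes = as.integer(n_genes),
    n_controls_per_plate = as.integer(n_controls_per_plate),
    mutants_per_plate = as.integer(mutants_per_plate),
    plates_per_day = as.integer(plates_per_day),
    replicates = as.integer(replicates),
    panel = panel,
    baseline_log_mean = baseline_log_mean[els],
    baseline_log_sd = baseline_log_sd[els],
    plate_effect_sd = plate_effect_sd,
    day_effect_sd = day_effect_sd,
    replicate_noise_sd = replicate_noise_sd,
    od_mean = od_mean, od_sd = od_sd,
    spike_fraction = spike_fraction,
    spike_effect_range = spike_effect_range,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a full plate-based ionomic screen
#'
#' Generates per-well concentrations for every plate of every replicate
#' batch under the log-normal model, together with the ground-truth table of
#' spiked gene x element perturbations. Deterministic for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `raw` (a `raw_screen_set`) and `truth` (data frame
#'   gene_id, element, log_fold, sign; empty when nothing is spiked).
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  els <- as.character(cfg$panel)
  nE <- length(els)
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  controls <- sprintf("CTRL%d", seq_len(cfg$n_controls_per_plate))

  # stream 1: ground truth (gene baselines + spikes)
  set.seed(seed_stream(cfg$seed, 1L))
  b <- matrix(stats::rnorm(cfg$n_genes * nE) *
                rep(cfg$baseline_log_sd, each = cfg$n_genes),
              cfg$n_genes, nE, dimnames = list(genes, els))
  spiked <- matrix(stats::runif(cfg$n_genes * nE) < cfg$spike_fraction,
                   cfg$n_genes, nE, dimnames = list(genes, els))
  lo <- log(cfg$spike_effect_range[1]); hi <- log(cfg$spike_effect_range[2])
  mag <- matrix(stats::runif(cfg$n_genes * nE, lo, hi), cfg$n_genes, nE)
  sgn <- matrix(sign(stats::runif(cfg$n_genes * nE) - 0.5), cfg$n_genes, nE)
  sgn[sgn == 0] <- 1
  spike <- ifelse(spiked, sgn * mag, 0)
  dimnames(spike) <- list(genes, els)

  idx <- which(spiked, arr.ind = TRUE)
  truth <- data.frame(
    gene_id = genes[idx[, 1]],
    element = els[idx[, 2]],
    log_fold = spike[spiked],
    sign = sign(spike[spiked]),
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$gene_id, truth$element), , drop = FALSE]
  rownames(truth) <- NULL

  # plate layout: genes chunked onto plates; one plate per chunk per replicate
  chunks <- split(genes, ceiling(seq_along(genes) / cfg$mutants_per_plate))
  n_plates <- length(chunks) * cfg$replicates
  plate_ids <- sprintf("P%04d", seq_len(n_plates))
  day_of_plate <- ceiling(seq_len(n_plates) / cfg$plates_per_day)
  day_ids <- sprintf("D%03d", day_of_plate)

  # stream 2: technical effects
  set.seed(seed_stream(cfg$seed, 2L))
  day_eff <- stats::rnorm(max(day_of_plate), 0, cfg$day_effect_sd)
  plate_eff <- stats::rnorm(n_plates, 0, cfg$plate_effect_sd)

  rows <- vector("list", n_plates)
  p <- 0L
  for (r in seq_len(cfg$replicates)) {
    for (ci in seq_along(chunks)) {
      p <- p + 1L
      strains <- c(controls, chunks[[ci]])
      rows[[p]] <- data.frame(
        plate_id = plate_ids[p],
        run_id = day_ids[p],
        well = VALID_WELLS[seq_along(strains)],
        strain_id = strains,
        role = c(rep("control", length(controls)),
                 rep("mutant", length(chunks[[ci]]))),
        replicate = r,
        stringsAsFactors = FALSE
      )
    }
  }
  wells <- do.call(rbind, rows)
  nW <- nrow(wells)

  # stream 3: measurement noise and OD
  set.seed(seed_stream(cfg$seed, 3L))
  od <- stats::rlnorm(nW, log(cfg$od_mean), cfg$od_sd)
  noise <- matrix(stats::rnorm(nW * nE, 0, cfg$replicate_noise_sd), nW, nE)

  gi <- match(wells$strain_id, genes)      # NA for controls
  tech <- day_eff[day_of_plate[match(wells$plate_id, plate_ids)]] +
    plate_eff[match(wells$plate_id, plate_ids)]
  conc <- matrix(0, nW, nE, dimnames = list(NULL, els))
  for (j in seq_len(nE)) {
    gene_part <- ifelse(is.na(gi), 0, b[gi, j] + spike[gi, j])
    conc[, j] <- exp(cfg$baseline_log_mean[j] + gene_part + tech + noise[, j]) * od
  }
  wells$od600 <- od
  wells <- cbind(wells, as.data.frame(conc))
  list(raw = new_raw_screen_set(wells, cfg$panel), truth = truth)
}

#' Simulate an interaction network around spiked genes
#'
#' Genes that share an identical spiked sign pattern are wired together with
#' probability `p_edge_within_pattern`; every other pair (including
#' background genes with no perturbation) with probability
#' `p_edge_background`. Edge types are assigned physical/genetic uniformly.
#'
#' @param truth Truth table from [simulate_screen()].
#' @param n_background_genes Number of unperturbed genes to add.
#' @param p_edge_within_pattern,p_edge_background Edge probabilities in
#'   `[0, 1]`.
#' @param seed Seed for the edge draws.
#' @return Data frame of interactions (`gene_a`, `gene_b`, `itype`).
#' @export
simulate_interaction_network <- function(truth, n_background_genes,
                                         p_edge_within_pattern,
                                         p_edge_background, seed = 1L) {
  stopifnot(p_edge_within_pattern >= 0, p_edge_within_pattern <= 1,
            p_edge_background >= 0, p_edge_background <= 1)
  pat <- c()
  if (nrow(truth) > 0) {
    pat <- tapply(paste0(truth$element, ":", truth$sign), truth$gene_id,
                  function(x) paste(sort(x), collapse = ";"))
  }
  bg <- if (n_background_genes > 0) {
    sprintf("BG%04d", seq_len(n_background_genes))
  } else character()
  all_genes <- c(names(pat), bg)
  patterns <- c(unname(pat), rep(NA_character_, length(bg)))
  n <- length(all_genes)
  if (n < 2) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      itype = character(), stringsAsFactors = FALSE))
  }
  set.seed(seed_stream(seed, 4L))
  pairs <- utils::combn(n, 2)
  same <- !is.na(patterns[pairs[1, ]]) & !is.na(patterns[pairs[2, ]]) &
    patterns[pairs[1, ]] == patterns[pairs[2, ]]
  p <- ifelse(same, p_edge_within_pattern, p_edge_background)
  keep <- stats::runif(ncol(pairs)) < p
  a <- all_genes[pairs[1, keep]]
  b <- all_genes[pairs[2, keep]]
  itype <- sample(c("physical", "genetic"), sum(keep), replace = TRUE)
  data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b), itype = itype,
             stringsAsFactors = FALSE)
}
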