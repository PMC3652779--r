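test_that("moderated Z matches the hand-computed robust standardization", {
  D <- matrix(c(1, 2, 3, 4, 100), ncol = 1,
              dimnames = list(paste0("g", 1:5), "Mn"))
  zt <- moderated_z(pheno_from_D(D))
  # median 3, MAD 1: Z = (x - 3) / 1.4826
  expect_equal(round(unname(zt$Z[, 1]), 3),
               c(-1.349, -0.674, 0, 0.674, 65.426))
  expect_equal(unname(zt$Z["g3", 1]), 0)  # gene at the median
})

test_that("moderated Z satisfies its algebraic identities per element", {
  cfg <- sim_config(n_genes = 50, spike_fraction = 0.05, seed = 17)
  odn <- od_normalize(simulate_screen(cfg)$raw)
  pheno <- summarize_phenotypes(odn, fit_plate_correction(odn))
  Z <- moderated_z(pheno)$Z
  for (j in seq_len(ncol(Z))) {
    expect_equal(median(Z[, j]), 0, tolerance = 1e-9)
    expect_equal(median(abs(Z[, j])), 1 / 1.4826, tolerance = 1e-9)
  }
})

test_that("zero across-gene MAD leaves an element undefined with a warning", {
  D <- matrix(c(1, 1, 1, 1, 5, 1, 2, 3, 4, 5), ncol = 2,
              dimnames = list(paste0("g", 1:5), c("Ca", "Mn")))
  expect_warning(zt <- moderated_z(pheno_from_D(D)), "Ca")
  expect_true(all(is.na(zt$Z[, "Ca"])))
  expect_false(anyNA(zt$Z[, "Mn"]))
})

test_that("q-values follow BH over the whole dataset and cutoffs are the extreme significant Z", {
  # invert the target p-values (0.001, 0.02, 0.9) into Z magnitudes
  p_target <- c(0.001, 0.02, 0.9)
  Z <- matrix(qnorm(1 - p_target / 2) * c(1, -1, 1), ncol = 1,
              dimnames = list(paste0("g", 1:3), "Mn"))
  zt <- structure(list(Z = Z, panel = element_panel("Mn")), class = "z_table")
  zt <- z_to_q(zt, alpha = 0.05)
  expect_equal(unname(zt$q[, 1]), c(0.003, 0.03, 0.9), tolerance = 1e-9)
  # two significant: one per direction; cutoffs equal those Z values
  expect_equal(unname(zt$cutoffs["pos_cut"]), Z[1, 1])
  expect_equal(unname(zt$cutoffs["neg_cut"]), Z[2, 1])

  # Z = 0 is never significant
  z0 <- structure(list(Z = matrix(0, 3, 1, dimnames = list(paste0("g", 1:3), "Mn")),
                       panel = element_panel("Mn")), class = "z_table")
  z0 <- z_to_q(z0)
  expect_equal(unname(z0$p[, 1]), rep(1, 3))
  expect_equal(unname(z0$q[, 1]), rep(1, 3))
  expect_equal(unname(z0$cutoffs), c(-Inf, Inf))
})

test_that("one huge outlier among nulls defines its side's cutoff", {
  set.seed(4)
  D <- matrix(c(rnorm(100, 10, 0.1), 50), ncol = 1,
              dimnames = list(paste0("g", 1:101), "Mn"))
  zt <- z_to_q(moderated_z(pheno_from_D(D)))
  sig <- which(zt$q[, 1] <= 0.05)
  expect_equal(names(sig), "g101")
  expect_equal(unname(zt$cutoffs["pos_cut"]), unname(zt$Z["g101", 1]))
  expect_equal(unname(zt$cutoffs["neg_cut"]), -Inf)
})

test_that("BH matches the sort-and-step oracle on random p-vectors", {
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, method = "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("the annealing filter enforces the 75% same-direction, 2xMAD rule", {
  # 5 genes, one element, 4 replicates; pooled median/MAD known by construction
  reps <- array(0, dim = c(5, 1, 4),
                dimnames = list(paste0("g", 1:5), "Mn", NULL))
  reps["g1", 1, ] <- c(8, 9, 10, 9)
  reps["g2", 1, ] <- c(10, 10.5, 9.5, 10)
  reps["g3", 1, ] <- c(10.3, 9.8, 10.2, 9.9)
  reps["g4", 1, ] <- c(30, 31, 29, 30)     # all far above
  reps["g5", 1, ] <- c(30, 31, 29, 9)      # 3/4 above = exactly 75%
  pheno <- pheno_from_reps(reps)
  zt <- z_to_q(moderated_z(pheno))

  pooled <- pheno$replicate_values$value
  m <- median(pooled); mad_e <- median(abs(pooled - m))
  pass <- annealing_filter(pheno, zt)
  # oracle: recompute the rule cell by cell
  for (g in paste0("g", 1:5)) {
    x <- reps[g, 1, ]
    expected <- mean(sign(x - m) == sign(zt$Z[g, 1]) &
                       abs(x - m) >= 2 * mad_e) >= 0.75
    expect_identical(unname(pass[g, 1]), expected)
  }
  expect_true(pass["g4", 1])   # 4/4 consistent
  expect_true(pass["g5", 1])   # 3/4 = 75% is inclusive
})

test_that("an even split of replicate directions fails the filter", {
  reps <- array(10, dim = c(4, 1, 4),
                dimnames = list(paste0("g", 1:4), "Mn", NULL))
  reps["g1", 1, ] <- c(1, 1, 19, 19)   # 2 up / 2 down
  reps["g2", 1, ] <- c(40, 41, 39, 40)
  reps["g3", 1, ] <- c(10, 10.1, 9.9, 10)
  reps["g4", 1, ] <- c(9.9, 10.1, 10, 10.05)
  pheno <- pheno_from_reps(reps)
  zt <- z_to_q(moderated_z(pheno))
  pass <- annealing_filter(pheno, zt)
  expect_false(pass["g1", 1])
  expect_true(pass["g2", 1])
})

test_that("percent change centers on the across-gene mean", {
  D <- matrix(c(1, 1, 2), ncol = 1, dimnames = list(paste0("g", 1:3), "Mn"))
  pheno <- pheno_from_D(D)   # sigma_tilde = 1, so s = D
  pc <- percent_change(pheno)
  expect_equal(unname(pc[, 1]), c(-0.25, -0.25, 0.5))

  cfg <- sim_config(n_genes = 40, spike_fraction = 0.05, seed = 19)
  odn <- od_normalize(simulate_screen(cfg)$raw)
  pheno2 <- summarize_phenotypes(odn, fit_plate_correction(odn))
  pc2 <- percent_change(pheno2)
  for (j in seq_len(ncol(pc2))) {
    expect_equal(mean(pc2[, j]), 0, tolerance = 1e-9)
  }
})

test_that("A/B/C groups follow the band hierarchy over significant elements", {
  sgn <- matrix(0L, 4, 2, dimnames = list(paste0("g", 1:4), c("Mn", "Cd")))
  pc <- matrix(0, 4, 2, dimnames = dimnames(sgn))
  sgn["g1", "Mn"] <- 1L; pc["g1", "Mn"] <- 0.90           # 90% -> B
  sgn["g2", "Mn"] <- 1L; pc["g2", "Mn"] <- 0.0            # 0% -> A
  sgn["g3", ] <- 1L; pc["g3", ] <- c(1.5, 0.1)            # any >= 100% -> C
  sgn["g4", "Cd"] <- -1L; pc["g4", ] <- c(5, -0.3)        # only sig element counts
  grp <- assign_groups(pc, sgn)
  expect_equal(unname(grp[c("g1", "g2", "g3", "g4")]), c("B", "A", "C", "B"))
  # boundaries are inclusive toward the extreme group
  sgn_b <- matrix(1L, 2, 1, dimnames = list(c("a", "b"), "Mn"))
  pc_b <- matrix(c(0.2, 1.0), 2, 1, dimnames = dimnames(sgn_b))
  expect_equal(unname(assign_groups(pc_b, sgn_b)), c("B", "C"))
})

test_that("sign patterns require significance, direction and the annealing pass", {
  Z <- matrix(c(5, 5, 2, -5), 4, 1, dimnames = list(paste0("g", 1:4), "Mn"))
  q <- matrix(c(0.01, 0.01, 0.2, 0.01), 4, 1, dimnames = dimnames(Z))
  ann <- matrix(c(TRUE, FALSE, TRUE, TRUE), 4, 1, dimnames = dimnames(Z))
  zt <- structure(list(Z = Z, q = q, alpha = 0.05,
                       panel = element_panel("Mn")), class = "z_table")
  sgn <- significance_pattern(zt, ann)
  expect_equal(unname(sgn[, 1]), c(1L, 0L, 0L, -1L))
})

test_that("raising one gene's phenotype never lowers its Z", {
  set.seed(23)
  for (rep in 1:10) {
    D <- matrix(rnorm(20, 10, 1), ncol = 1,
                dimnames = list(paste0("g", 1:20), "Mn"))
    target <- "g1"  # keep clear of the median-defining genes
    D[target, 1] <- max(D) + 1
    z1 <- moderated_z(pheno_from_D(D))$Z[target, 1]
    D2 <- D
    D2[target, 1] <- D[target, 1] + runif(1, 0, 5)
    z2 <- moderated_z(pheno_from_D(D2))$Z[target, 1]
    expect_gte(z2, z1)
  }
})

test_that("null screens produce almost no significant calls", {
  frac <- vapply(1:10, function(i) {
    cfg <- sim_config(n_genes = 40, spike_fraction = 0, seed = 500 + i)
    odn <- od_normalize(simulate_screen(cfg)$raw)
    pheno <- summarize_phenotypes(odn, fit_plate_correction(odn))
    calls <- call_significance(pheno)
    mean(calls$sign != 0)
  }, numeric(1))
  n_cells <- 40 * 14
  se <- sqrt(0.05 * 0.95 / (n_cells * length(frac)))
  expect_lte(mean(frac), 0.05 + 3 * se)
})
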