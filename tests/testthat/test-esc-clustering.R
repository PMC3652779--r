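random_sign_matrix <- function(n_genes, n_elements, force_nonzero = TRUE) {
  sgn <- matrix(sample(c(-1L, 0L, 1L), n_genes * n_elements, replace = TRUE),
                n_genes, n_elements,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                paste0("E", seq_len(n_elements))))
  if (force_nonzero) {
    zero_rows <- rowSums(sgn != 0) == 0
    sgn[zero_rows, 1] <- 1L
  }
  sgn
}

test_that("genes are partitioned by exact sign-pattern equality", {
  sgn <- matrix(0L, 5, 2, dimnames = list(paste0("g", 1:5), c("Mn", "Cd")))
  sgn[1:3, 1] <- 1L          # pattern A x3
  sgn[4:5, 2] <- -1L         # pattern B x2
  cs <- esc_cluster(call_set_from_sign(sgn), min_size = 3)
  expect_length(cs$clusters, 1)
  expect_setequal(cs$clusters[[1]]$members, paste0("g", 1:3))
  expect_setequal(cs$unclustered, paste0("g", 4:5))
})

test_that("clustering matches the dictionary oracle on random sign matrices", {
  set.seed(31)
  for (i in 1:50) {
    sgn <- random_sign_matrix(sample(4:15, 1), sample(2:5, 1))
    min_size <- sample(1:3, 1)
    cs <- esc_cluster(call_set_from_sign(sgn), min_size = min_size)
    oracle <- esc_oracle(sgn, min_size)
    got <- lapply(cs$clusters, function(cl) cl$members)
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(unname(oracle$clustered), paste, character(1),
                           collapse = ","))
    expect_equal(cs$unclustered, oracle$unclustered)
    # partition property
    all_members <- c(unlist(got, use.names = FALSE), cs$unclustered)
    expect_setequal(all_members, rownames(sgn))
    expect_equal(anyDuplicated(all_members), 0)
    # every member's sign vector equals the cluster pattern
    for (cl in cs$clusters) {
      for (m in cl$members) {
        expect_identical(unname(sgn[m, ]), unname(cl$signs))
      }
    }
  }
})

test_that("cluster order is by size then pattern key, invariant to input order", {
  set.seed(37)
  sgn <- random_sign_matrix(30, 3)
  cs1 <- esc_cluster(call_set_from_sign(sgn), min_size = 2)
  perm <- sample(nrow(sgn))
  cs2 <- esc_cluster(call_set_from_sign(sgn[perm, , drop = FALSE]), min_size = 2)
  expect_equal(lapply(cs1$clusters, function(cl) cl$members),
               lapply(cs2$clusters, function(cl) cl$members))
  sizes <- vapply(cs1$clusters, function(cl) length(cl$members), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("cluster median profiles equal the sort-and-pick oracle", {
  sgn <- matrix(1L, 3, 1, dimnames = list(c("a", "b", "c"), "Mn"))
  cs <- call_set_from_sign(sgn)
  cs$Z <- matrix(c(4, 6, 8), 3, 1, dimnames = dimnames(sgn))
  clusters <- cluster_medians(esc_cluster(cs, min_size = 3), cs)
  expect_equal(unname(clusters$median_profiles[1, 1]), 6)

  set.seed(41)
  for (i in 1:20) {
    sgn <- random_sign_matrix(12, 4)
    cset <- call_set_from_sign(sgn)
    cset$Z <- matrix(rnorm(48), 12, 4, dimnames = dimnames(sgn))
    cl <- cluster_medians(esc_cluster(cset, min_size = 2), cset)
    for (nm in names(cl$clusters)) {
      members <- cl$clusters[[nm]]$members
      for (j in seq_len(4)) {
        v <- sort(cset$Z[members, j])
        n <- length(v)
        oracle <- unname(if (n %% 2 == 1) v[(n + 1) / 2] else mean(v[n / 2 + 0:1]))
        expect_equal(unname(cl$median_profiles[nm, j]), oracle)
      }
    }
  }
})

test_that("missing cluster members in the Z table are an error naming the gene", {
  sgn <- matrix(1L, 3, 1, dimnames = list(c("a", "b", "c"), "Mn"))
  cs <- call_set_from_sign(sgn)
  clusters <- esc_cluster(cs, min_size = 3)
  Zpart <- cs$Z[c("a", "b"), , drop = FALSE]
  expect_error(cluster_medians(clusters, Zpart), "c")
})

test_that("hierarchical ordering is complete-linkage on Euclidean distances", {
  # close pair must be adjacent among three clusters at distances (1, 10, 10)
  prof <- matrix(c(0, 0, 1, 0, 10, 0), 3, 2, byrow = TRUE,
                 dimnames = list(c("C1", "C2", "C3"), c("E1", "E2")))
  cs <- structure(list(clusters = list(), unclustered = character(),
                       panel = element_panel(c("E1", "E2")),
                       median_profiles = prof,
                       row_order = integer(), col_order = integer()),
                  class = "cluster_set")
  cs <- hierarchical_order(cs)
  pos <- match(1:2, cs$row_order)
  expect_equal(abs(diff(pos)), 1)
  expect_true(all(sort(cs$row_order) == 1:3))
  expect_true(all(sort(cs$col_order) == 1:2))

  # merge heights equal the brute-force agglomeration oracle
  set.seed(43)
  for (i in 1:20) {
    X <- matrix(rnorm(sample(3:6, 1) * 4), ncol = 4)
    rownames(X) <- paste0("C", seq_len(nrow(X)))
    h <- hclust(dist(X), method = "complete")$height
    expect_equal(sort(h), complete_linkage_heights(X), tolerance = 1e-10)
  }

  # duplicate profiles merge first at height zero
  Xdup <- rbind(prof, C4 = prof["C1", ])
  hd <- hclust(dist(Xdup), method = "complete")
  expect_equal(min(hd$height), 0)
})

test_that("heatmap export bands cells against the dataset cutoffs", {
  prof <- matrix(c(-4, 0, 3.5, 2), 2, 2, byrow = TRUE,
                 dimnames = list(c("C1", "C2"), c("Mn", "Cd")))
  cs <- structure(list(
    clusters = list(C1 = list(pattern = "-0", members = c("a", "b", "c")),
                    C2 = list(pattern = "0+", members = c("d", "e", "f"))),
    unclustered = character(), panel = element_panel(c("Mn", "Cd")),
    median_profiles = prof, row_order = 1:2, col_order = 1:2),
    class = "cluster_set")
  names(cs$clusters) <- c("C1", "C2")
  rownames(cs$median_profiles) <- c("C1", "C2")
  tab <- export_heatmap_table(cs, thresholds = c(-3.328, 3.473))
  get_band <- function(cl, el) tab$band[tab$cluster == cl & tab$element == el]
  expect_equal(get_band("C1", "Mn"), "sig_neg")   # -4 < -3.328
  expect_equal(get_band("C2", "Mn"), "sig_pos")   # 3.5 > 3.473
  expect_equal(get_band("C1", "Cd"), "pos")       # 0 lands in [0, pos_cut)
  expect_equal(get_band("C2", "Cd"), "pos")
  expect_equal(tab$size[tab$cluster == "C1"], c(3L, 3L))
})

test_that("the pattern space grows as 3^E", {
  expect_equal(pattern_space_size(2), 9)
  expect_equal(pattern_space_size(panel_oe()), 3^17)
})
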