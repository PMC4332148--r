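test_that("max-normalization puts each protein's maximum at exactly 1", {
  mat <- rbind(A = c(2, 4, 1), B = c(5, 5, 5), C = c(NA, 3, NA),
               D = c(NA, NA, NA))
  nn <- max_normalize(mat)
  expect_equal(unname(nn$values["A", ]), c(0.5, 1, 0.25))
  expect_equal(unname(nn$values["B", ]), c(1, 1, 1))
  expect_equal(unname(nn$values["C", ]), c(NA, 1, NA))
  expect_equal(nn$dropped, "D")
  expect_true(all(apply(nn$values, 1, max, na.rm = TRUE) == 1))
})

test_that("supervised clustering separates block-structured R2 rows", {
  set.seed(11)
  block <- function(hot, n) {
    m <- matrix(runif(n * 8, 0, 0.15), n, 8)
    m[, hot] <- runif(n * length(hot), 0.85, 1)
    m
  }
  r2 <- rbind(block(1:2, 4), block(3:4, 4), block(5:6, 4))
  rownames(r2) <- paste0("P", 1:12)
  colnames(r2) <- paste0("ref", 1:8)
  sup <- supervised_cluster(r2)
  k3 <- cut_clusters(sup, 3)
  planted <- rep(1:3, each = 4)
  expect_true(same_partition(k3, planted))
  # duplicated rows merge first, at height zero
  r2dup <- rbind(r2, P1bis = r2["P1", ])
  supd <- supervised_cluster(r2dup)
  expect_equal(min(supd$hclust$height), 0)
  first <- hclust_member_sets(supd$hclust)[[1]]
  expect_setequal(rownames(r2dup)[first], c("P1", "P1bis"))
  expect_error(supervised_cluster(r2[1, , drop = FALSE]), "2 rows")
})

test_that("Pearson(n) PCA: eigen oracle on a 4x4 toy, symmetry, invariance", {
  X <- matrix(c(1, 2, 3, 4,
                2, 1, 4, 3,
                1, 3, 2, 5,
                5, 4, 1, 2), 4, 4)
  dimnames(X) <- list(paste0("o", 1:4), paste0("v", 1:4))
  p <- pca_pearson(X)
  expect_equal(sum(p$explained), 1, tolerance = 1e-12)
  # oracle: hand-computed population correlation matrix, brute eigen
  C <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) C[i, j] <- oracle_pearson(X[, i], X[, j])
  ev <- eigen(C, symmetric = TRUE)$values
  expect_equal(sort(p$explained, decreasing = TRUE) * sum(ev),
               sort(ev, decreasing = TRUE), tolerance = 1e-10)

  # two perfectly correlated variables load the first component equally
  Y <- cbind(v1 = c(1, 2, 3, 5), v2 = 2 * c(1, 2, 3, 5) + 1,
             v3 = c(4, 1, 3, 2))
  rownames(Y) <- paste0("o", 1:4)
  py <- pca_pearson(Y)
  expect_equal(abs(py$loadings["v1", 1]), abs(py$loadings["v2", 1]),
               tolerance = 1e-10)

  # scores are invariant to positive per-variable affine rescaling
  set.seed(23)
  Z <- matrix(rnorm(30), 6, 5,
              dimnames = list(paste0("o", 1:6), paste0("v", 1:5)))
  a <- runif(5, 0.5, 4)
  b <- rnorm(5)
  Z2 <- sweep(sweep(Z, 2, a, `*`), 2, b, `+`)
  expect_equal(pca_pearson(Z)$scores, pca_pearson(Z2)$scores,
               tolerance = 1e-8)

  # zero-variance variable is dropped and reported
  Z3 <- cbind(Z, vconst = rep(1, 6))
  expect_equal(pca_pearson(Z3)$dropped, "vconst")
})

test_that("UPGMA on 1 - r: degenerate pairs and dissimilarity bounds", {
  mat <- rbind(A = c(1, 2, 3, 4), B = c(2, 4, 6, 8),    # r = 1
               C = c(4, 3, 2, 1),                        # r = -1 vs A
               D = c(9, 1, 7, 3))
  d <- ahc_upgma(mat)
  expect_equal(min(d$merges$height), 0, tolerance = 1e-12)
  first <- hclust_member_sets(d$hclust)[[1]]
  expect_setequal(d$leaves[first], c("A", "B"))
  # anticorrelated pair has dissimilarity 2
  d2 <- ahc_upgma(mat[c("A", "C"), ])
  expect_equal(d2$merges$height, 2, tolerance = 1e-12)
  # zero-variance rows get maximal dissimilarity, with a report
  mat3 <- rbind(A = c(1, 2, 3), Z = c(5, 5, 5), B = c(2, 4, 6))
  d3 <- ahc_upgma(mat3)
  expect_equal(d3$undefined_pairs, 2)
})

test_that("UPGMA merge sequence matches the exhaustive oracle", {
  set.seed(37)
  for (trial in 1:5) {
    n <- sample(6:10, 1)
    X <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(paste0("L", seq_len(n)), NULL))
    dend <- ahc_upgma(X)
    # oracle works on the same dissimilarity definition
    Xi <- X
    r <- cor(t(Xi))
    D <- 1 - r
    diag(D) <- 0
    want <- oracle_upgma(D)
    got_sets <- hclust_member_sets(dend$hclust)
    for (k in seq_along(want)) {
      expect_equal(dend$merges$height[k], want[[k]]$height, tolerance = 1e-9)
      expect_setequal(got_sets[[k]], want[[k]]$members)
    }
    # heights are the average pairwise dissimilarity of the merged groups
    hm <- dend$hclust$merge
    for (k in seq_len(nrow(hm))) {
      left <- if (hm[k, 1] < 0) -hm[k, 1] else got_sets[[hm[k, 1]]]
      right <- if (hm[k, 2] < 0) -hm[k, 2] else got_sets[[hm[k, 2]]]
      expect_equal(dend$merges$height[k], mean(D[left, right]),
                   tolerance = 1e-9)
    }
    # UPGMA heights are monotone non-decreasing
    expect_true(all(diff(dend$merges$height) > -1e-12))
  }
})

test_that("newick export preserves the ultrametric leaf depths", {
  mat <- rbind(A = c(1, 2, 3, 4), B = c(1.1, 2, 3, 4.2), C = c(4, 3, 2, 1),
               D = c(8, 1, 6, 2))
  nwk <- as_newick(ahc_upgma(mat))
  expect_match(nwk, "^\\(.*\\);$")
  for (leaf in c("A", "B", "C", "D")) expect_match(nwk, leaf, fixed = TRUE)
})

test_that("default study simulation clusters into the three planted groups", {
  cat6 <- default_catalog()
  groups <- list(
    immuno = subunit_accessions(c("β1i", "β2i", "β5i", "PA28α", "PA28β"),
                                cat6$catalog),
    standard = subunit_accessions(c("β1", "β2", "β5", "PI31", "PA200"),
                                  cat6$catalog),
    core = subunit_accessions(
      c(paste0("α", 1:7), paste0("β", c(3, 4, 6, 7)),
        paste0("Rpt", 1:6), paste0("Rpn", c(1:3, 5:14))), cat6$catalog))
  planted <- rep(seq_along(groups), lengths(groups))
  members <- unlist(groups)

  sim <- simulate_apms(default_apms_model(seed = 77))
  pai <- quantify(sim$peptide_table)
  refs <- build_reference_abundances(pai, cat6$complexes, cat6$catalog)
  cm <- correlation_matrix(pai, refs, members)
  sup <- supervised_cluster(cm$r2)
  expect_true(same_partition(cut_clusters(sup, 3)[members], planted))

  norm <- max_normalize(pai)
  dend <- ahc_upgma(norm$values[members, ])
  expect_true(same_partition(cut_clusters(dend, 3)[members], planted))
})
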