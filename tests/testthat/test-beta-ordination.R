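# Dissimilarities, PCoA and PERMANOVA.

test_that("log transform is exact and monotone", {
  expect_equal(log_transform_counts(0), 0)
  expect_equal(log_transform_counts(exp(1) - 1), 1)
  set.seed(21)
  x <- sort(runif(50, 0, 100))
  expect_true(all(diff(log_transform_counts(x)) > 0))
})

test_that("pairwise dissimilarities match hand computations", {
  expect_equal(bray_curtis(c(3, 1), c(3, 1)), 0)
  expect_equal(bray_curtis(c(2, 0), c(0, 5)), 1)
  expect_equal(bray_curtis(c(1, 1), c(1, 3)), 2 / 6)
  expect_equal(jaccard_dissimilarity(c(2, 5, 0), c(9, 1, 0)), 0)
  expect_equal(jaccard_dissimilarity(c(1, 1, 0), c(0, 1, 1)), 2 / 3)
  expect_equal(jaccard_dissimilarity(c(1, 0), c(0, 1)), 1)
  expect_equal(morisita_horn(c(2, 4), 3 * c(2, 4)), 0)
  expect_equal(morisita_horn(c(1, 0), c(0, 1)), 1)
  expect_equal(morisita_horn(c(1, 1), c(1, 0)), 1 / 3)
  expect_error(bray_curtis(c(0, 0), c(0, 0)),
               class = "bld_error_undefined_distance")
  expect_error(jaccard_dissimilarity(c(0, 0), c(0, 0)),
               class = "bld_error_undefined_distance")
})

test_that("metric axioms hold on random pairs", {
  set.seed(22)
  for (rep in 1:500) {
    x <- rpois(15, 4)
    y <- rpois(15, 4)
    if (sum(x) == 0) x[1] <- 1
    if (sum(y) == 0) y[1] <- 1
    for (f in list(bray_curtis, jaccard_dissimilarity, morisita_horn)) {
      d <- f(x, y)
      expect_gte(d, -1e-12)
      expect_lte(d, 1 + 1e-12)
      expect_equal(f(x, x), 0, tolerance = 1e-12)
      expect_equal(d, f(y, x))
    }
  }
})

test_that("matrix route (vegdist) agrees with the scalar formulas", {
  set.seed(23)
  tab <- random_count_table(n_samples = 10, n_taxa = 30)
  lt <- log_transform_counts(tab)
  d_bray <- as.matrix(beta_dissimilarity(tab, "bray"))
  d_jac <- as.matrix(beta_dissimilarity(tab, "jaccard"))
  d_mh <- as.matrix(beta_dissimilarity(tab, "morisita_horn"))
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_equal(d_bray[i, j], bray_curtis(lt[i, ], lt[j, ]))
      expect_equal(d_jac[i, j], jaccard_dissimilarity(lt[i, ], lt[j, ]))
      expect_equal(d_mh[i, j], morisita_horn(tab[i, ], tab[j, ]))
    }
  }
})

test_that("PCoA recovers Euclidean configurations", {
  # four points on a line: one dominant axis, exact distance reconstruction
  d <- dist(matrix(c(0, 1, 2, 3), ncol = 1))
  ord <- pcoa_ordination(d)
  expect_equal(sum(ord$eigenvalues > 1e-8), 1)
  expect_equal(as.matrix(dist(ord$coordinates)), as.matrix(d),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(ord$reconstruction_rmse, 1e-9)
  # equidistant points embed as a regular simplex: equal positive eigenvalues
  ord <- pcoa_ordination(matrix(1, 4, 4) - diag(4))
  pos <- ord$eigenvalues[ord$eigenvalues > 1e-8]
  expect_equal(length(pos), 3)
  expect_equal(max(pos) - min(pos), 0, tolerance = 1e-9)
  # a 2-D configuration: two axes carry all positive inertia
  set.seed(24)
  pts <- matrix(rnorm(14), ncol = 2)
  ord <- pcoa_ordination(dist(pts))
  expect_equal(sum(ord$proportion_explained[1:2]), 1, tolerance = 1e-9)
  expect_equal(as.matrix(dist(ord$coordinates)), as.matrix(dist(pts)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("PCoA matches cmdscale and reports negative eigenvalues", {
  set.seed(25)
  tab <- random_count_table(8, 20)
  d <- beta_dissimilarity(tab, "bray")
  ord <- pcoa_ordination(d)
  cmd <- cmdscale(d, k = 2, eig = TRUE)
  expect_equal(abs(ord$coordinates[, 1]), abs(cmd$points[, 1]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sort(ord$eigenvalues), sort(cmd$eig), tolerance = 1e-8)
  # a triangle-inequality violation forces a negative eigenvalue, which is
  # reported rather than hidden
  bad <- matrix(1, 4, 4) - diag(4)
  bad[1, 2] <- bad[2, 1] <- 2.2
  ord_bad <- pcoa_ordination(bad)
  expect_lt(min(ord_bad$eigenvalues), -1e-8)
  expect_gt(ord_bad$reconstruction_rmse, 0)
  expect_error(pcoa_ordination(dist(matrix(1:2, ncol = 1))),
               class = "bld_error_too_few_samples")
})

test_that("PERMANOVA matches adonis2 and the definition-based oracle", {
  set.seed(26)
  tab <- random_count_table(18, 25)
  labels <- rep(c("a", "b", "c"), each = 6)
  d <- beta_dissimilarity(tab, "bray")
  res <- permanova(d, labels, n_permutations = 199, seed = 1)
  ad <- vegan::adonis2(d ~ labels, permutations = 199)
  expect_equal(res$pseudo_F, ad$F[1])
  expect_equal(res$R2, ad$R2[1])
  expect_equal(res$pseudo_F, oracle_pseudo_f(as.matrix(d), labels))
  # invariance to consistent sample reordering
  perm <- sample(18)
  res2 <- permanova(as.matrix(d)[perm, perm], labels[perm],
                    n_permutations = 99, seed = 1)
  expect_equal(res2$pseudo_F, res$pseudo_F)
  # invariance to renaming the groups
  res3 <- permanova(d, c(a = "x", b = "y", c = "z")[labels],
                    n_permutations = 99, seed = 1)
  expect_equal(res3$pseudo_F, res$pseudo_F)
})

test_that("exact PERMANOVA enumeration equals the brute-force labeling oracle", {
  # two tight pairs: within-pair distance 0, across-pair distance 1
  dmat <- matrix(1, 4, 4)
  dmat[1, 2] <- dmat[2, 1] <- dmat[3, 4] <- dmat[4, 3] <- 0
  diag(dmat) <- 0
  labels <- c("A", "A", "B", "B")
  res <- permanova(dmat, labels, exact = TRUE)
  expect_true(is.infinite(res$pseudo_F))
  # oracle: enumerate all choose(4,2) labelings directly
  f_obs <- oracle_pseudo_f(dmat, labels)
  assignments <- combn(4, 2, simplify = FALSE)
  f_all <- vapply(assignments, function(a) {
    lab <- ifelse(seq_len(4) %in% a, "A", "B")
    oracle_pseudo_f(dmat, lab)
  }, numeric(1))
  expect_equal(res$p_value, mean(f_all >= f_obs))
  expect_equal(res$p_value, 1 / 3)   # both the A/B split and its mirror tie
})

test_that("PERMANOVA respects strata and the +1 p-value floor", {
  set.seed(27)
  tab <- random_count_table(12, 20)
  d <- beta_dissimilarity(tab, "bray")
  labels <- rep(c("a", "b"), 6)
  strata <- rep(1:6, each = 2)
  res <- permanova(d, labels, n_permutations = 99, seed = 2, strata = strata)
  expect_gte(res$p_value, 1 / 100)
  expect_lte(res$p_value, 1)
  expect_equal(permanova(d, labels, n_permutations = 99, seed = 2,
                         strata = strata)$p_value, res$p_value)
  # cleanly separated groups: only partition-preserving relabelings tie, so
  # p is small but bounded below by the +1 floor
  dmat <- as.matrix(dist(c(0, 0.1, 0.2, 5, 5.1, 5.2, 5.3, 0.05)))
  lab2 <- c("x", "x", "x", "y", "y", "y", "y", "x")
  res2 <- permanova(dmat, lab2, n_permutations = 999, seed = 3)
  expect_lt(res2$p_value, 0.05)
  expect_gte(res2$p_value, 1 / 1000)
})
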