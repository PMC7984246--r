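test_that("feature matrix spreads variant keys with zero-fill", {
  tab <- tibble::tibble(
    population_id = c("p1", "p2", "p1", "p2"),
    chrom = "c1", pos = c(1, 2, 3, 3), ref = "A",
    alt = c("T", "T", "G", "G"),
    proportion = c(1, 1, 0.5, 0.9))
  m <- variant_feature_matrix(tab)
  expect_equal(dim(m), c(2, 3))
  expect_equal(m["p1", "c1:1:A:T"], 1)
  expect_equal(m["p2", "c1:1:A:T"], 0)
  # shared variant 0.5 vs 0.9 -> distance 0.4 on that axis
  expect_equal(abs(m["p1", "c1:3:A:G"] - m["p2", "c1:3:A:G"]), 0.4)

  two <- variant_feature_matrix(tab[1:2, ])
  expect_equal(unname(two), rbind(c(1, 0), c(0, 1)))
  expect_equal(as.numeric(euclidean_distances(two)), sqrt(2))

  dup <- tab; dup$pos[2] <- 1; dup$population_id[2] <- "p1"
  expect_error(variant_feature_matrix(dup), class = "gxediv_input_error")
})

test_that("Euclidean distances are metric and match hand values", {
  m <- rbind(a = c(0, 0), b = c(3, 4))
  expect_equal(as.numeric(euclidean_distances(m)), 5)
  expect_equal(as.numeric(euclidean_distances(rbind(c(1, 2), c(1, 2)))), 0)
  withr::with_seed(41, x <- matrix(rnorm(15), 5))
  d <- as.matrix(euclidean_distances(x))
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("PERMANOVA reproduces the hand-computed partition and matches vegan", {
  d <- euclidean_distances(matrix(c(0, 2, 10, 12), ncol = 1))
  g <- c("a", "a", "b", "b")
  res <- permanova(d, g, n_perm = 999, seed = 1)
  expect_equal(res$pseudo_F, 50)
  expect_equal(res$R2, 100 / 104)
  expect_equal(res$df, c(df1 = 1L, df2 = 2L))
  expect_gte(res$p_value, 1 / 1000)

  # independent oracle: vegan's adonis2 on a larger random problem
  withr::with_seed(42, {
    x <- matrix(rnorm(10 * 4), nrow = 10)
    x[6:10, 1] <- x[6:10, 1] + 2
  })
  grp <- rep(c("u", "v"), each = 5)
  dd <- euclidean_distances(x)
  mine <- permanova(dd, grp, n_perm = 999, seed = 3)
  ref <- vegan::adonis2(dd ~ grp, permutations = 999)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)
  expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 0.1)
})

test_that("on 1-D data the pseudo-F equals the classical ANOVA F", {
  withr::with_seed(43, {
    for (i in 1:10) {
      v <- rnorm(12)
      g <- sample(rep(c("a", "b", "c"), 4))
      ps <- permanova(euclidean_distances(matrix(v, ncol = 1)), g,
                      n_perm = 9, seed = i)
      expect_equal(ps$pseudo_F, lm_f_test(v, g)$statistic, tolerance = 1e-10)
    }
  })
})

test_that("PERMANOVA p is permutation-invariant and F is translation-invariant", {
  withr::with_seed(44, x <- matrix(rnorm(16), nrow = 8))
  g <- rep(c("a", "b"), each = 4)
  d <- euclidean_distances(x)
  base <- permanova(d, g, n_perm = 499, seed = 5)

  # permute samples and labels identically
  perm <- c(3, 1, 4, 2, 8, 5, 7, 6)
  d2 <- as.matrix(d)[perm, perm]
  same <- permanova(d2, g[perm], n_perm = 499, seed = 5)
  expect_equal(same$pseudo_F, base$pseudo_F, tolerance = 1e-12)

  # translating the point cloud leaves distances, hence F, unchanged
  shifted <- permanova(euclidean_distances(x + 7), g, n_perm = 9, seed = 1)
  expect_equal(shifted$pseudo_F, base$pseudo_F, tolerance = 1e-12)

  expect_error(permanova(d, rep("a", 8)), class = "gxediv_input_error")
})

test_that("beta-dispersion matches the hand ANOVA and vegan's centroid version", {
  # 1-D groups {0,4} and {10,11}: distances to centroid 2,2,0.5,0.5
  d <- euclidean_distances(matrix(c(0, 4, 10, 11), ncol = 1))
  g <- c("a", "a", "b", "b")
  disp <- beta_dispersion(d, g)
  expect_equal(sort(tidy(disp)$distance_to_centroid), c(0.5, 0.5, 2, 2))
  # the hand ANOVA on {2,2,0.5,0.5} has zero residual: F diverges
  expect_gt(glance(disp)$statistic, 1e10)

  withr::with_seed(45, x <- matrix(rnorm(24), nrow = 8))
  g8 <- rep(c("u", "v"), each = 4)
  mine <- beta_dispersion(euclidean_distances(x), g8)
  ref <- vegan::betadisper(euclidean_distances(x), g8, type = "centroid")
  expect_equal(sort(tidy(mine)$distance_to_centroid),
               sort(unname(ref$distances)), tolerance = 1e-8)
  ref_aov <- anova(ref)
  expect_equal(glance(mine)$statistic, ref_aov$`F value`[1],
               tolerance = 1e-8)
  expect_true(all(tidy(mine)$distance_to_centroid >= 0))

  # two groups with identical internal geometry -> between-group F of 0
  shape <- rbind(c(-1, 0), c(1, 0), c(0, 1.5))
  sym <- rbind(shape, sweep(shape, 2, c(10, 0), "+"))
  even <- beta_dispersion(euclidean_distances(sym), rep(c("a", "b"), each = 3))
  expect_lt(abs(glance(even)$statistic), 1e-8)
})

test_that("NMDS embeds rank structure with seeded reproducibility", {
  # three equidistant points embed exactly in 2-D
  tri <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), nrow = 3)
  ord <- suppressWarnings(nmds_ordination(tri, k = 2, seed = 1))
  expect_lt(ord$stress, 1e-3)

  withr::with_seed(46, x <- matrix(rnorm(14 * 3), nrow = 14))
  d <- euclidean_distances(x)
  ord2 <- nmds_ordination(d, k = 2, seed = 2)
  if (ord2$stress < 0.05) {
    emb <- dist(as.matrix(ord2$points[, c("NMDS1", "NMDS2")]))
    expect_gt(cor(as.numeric(d), as.numeric(emb), method = "spearman"), 0.95)
  }

  rep1 <- nmds_ordination(d, k = 2, seed = 9)
  rep2 <- nmds_ordination(d, k = 2, seed = 9)
  pro <- vegan::procrustes(as.matrix(rep1$points[, c("NMDS1", "NMDS2")]),
                           as.matrix(rep2$points[, c("NMDS1", "NMDS2")]))
  expect_lt(pro$ss, 1e-8)

  expect_error(nmds_ordination(matrix(0, 3, 3)), class = "gxediv_input_error")
})

test_that("a treatment-diagnostic variant drives PERMANOVA significance", {
  hits <- 0L
  for (s in 1:20) {
    sc <- variant_scenario(
      n_populations = 6, mean_variants_per_population = 2.5,
      shared_variant_spec = tibble::tibble(
        variant_id = "diag", treatment = "homogeneous",
        fraction = 1, proportion = 0.6),
      seed = s)
    tab <- simulate_variant_tables(sc)
    fm <- variant_feature_matrix(tab)
    grp <- tab$treatment[match(rownames(fm), tab$population_id)]
    res <- permanova(euclidean_distances(fm), grp, n_perm = 999, seed = s)
    if (res$p_value <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.95)
})
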