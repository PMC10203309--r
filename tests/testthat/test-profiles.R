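test_that("autoscaled PCA reconstructs scores and handles rank-1 data", {
  X <- toy_matrix(20, 6, seed = 40)
  pf <- pca_fit(X, n_components = 4)
  Xs <- scale(X)
  expect_equal(pf$scores, Xs %*% pf$loadings, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pf$variance_explained) <= 1e-12))
  # orthogonal components
  G <- crossprod(pf$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)

  # rank-1 data: PC1 captures all the variance
  base <- rnorm(15)
  X1 <- outer(base, c(1, 2, -1, 0.5))
  X1 <- X1 + 0   # exact rank 1
  colnames(X1) <- paste0("V", 1:4); rownames(X1) <- paste0("S", 1:15)
  pf1 <- pca_fit(X1, n_components = 2)
  expect_equal(pf1$variance_explained[1], 1, tolerance = 1e-10)

  # permuting samples permutes scores identically
  perm <- sample(20)
  pf2 <- pca_fit(X[perm, ], n_components = 4)
  expect_equal(abs(pf2$scores), abs(pf$scores[perm, ]), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pca_fit(X[1:2, ]), "3 samples")
  expect_warning(pca_fit(cbind(X, C = rep(1, 20))), "constant")
})

test_that("Hotelling reduced-T2 flags constructed outliers but not spherical data", {
  set.seed(41)
  X <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(paste0("S", 1:40), paste0("V", 1:5)))
  pf <- pca_fit(X, n_components = 2)
  ht <- hotelling_outliers(pf)
  expect_true(all(ht$t2 >= 0))
  expect_lt(mean(ht$outlier), 0.05 + 1e-9)

  # one sample displaced 10 SD along the first axis
  Xo <- X
  Xo[7, ] <- Xo[7, ] + 10 * pf$loadings[, 1] * apply(X, 2, sd)
  pfo <- pca_fit(Xo, n_components = 2)
  hto <- hotelling_outliers(pfo)
  expect_true(hto$outlier[7])
  expect_error(hotelling_outliers(pf, threshold = 0), "positive")
})

test_that("spherical-data flag rate stays below 5% across seeds", {
  rates <- sapply(1:5, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(60 * 8), 60, 8,
                dimnames = list(paste0("S", 1:60), paste0("V", 1:8)))
    mean(hotelling_outliers(pca_fit(X, n_components = 2))$outlier)
  })
  expect_lt(mean(rates), 0.05)
})

test_that("permutation test detects separation and matches exhaustive enumeration", {
  set.seed(43)
  scores <- matrix(rnorm(24 * 2), 24, 2)
  groups <- rep(c("a", "b"), each = 12)
  sep <- scores
  sep[groups == "a", 1] <- sep[groups == "a", 1] + 5
  res <- permutation_group_test(sep, groups, n_perm = 999, seed = 44)
  expect_equal(res$p, 1 / 1000)

  # null: p roughly uniform over repeats
  ps <- sapply(1:40, function(s) {
    permutation_group_test(matrix(rnorm(20 * 2), 20, 2),
                           rep(c("a", "b"), each = 10),
                           n_perm = 199, seed = s)$p
  })
  expect_lt(abs(mean(ps) - 0.5), 0.15)

  # n = 8: Monte-Carlo p within 2 MC SEs of the exhaustive permutation p
  sc8 <- matrix(rnorm(8 * 2, sd = 1), 8, 2)
  g8 <- rep(c("a", "b"), each = 4)
  stat <- function(g) {
    ma <- colMeans(sc8[g == "a", , drop = FALSE])
    mb <- colMeans(sc8[g == "b", , drop = FALSE])
    sqrt(sum((ma - mb)^2))
  }
  obs <- stat(g8)
  combos <- combn(8, 4)
  ex <- apply(combos, 2, function(ix) {
    g <- rep("b", 8); g[ix] <- "a"
    stat(g)
  })
  p_ex <- mean(ex >= obs - 1e-12)
  n_perm <- 2000
  res8 <- permutation_group_test(sc8, g8, n_perm = n_perm, seed = 45)
  mc_se <- sqrt(p_ex * (1 - p_ex) / n_perm)
  expect_lt(abs(res8$p - p_ex), 2 * mc_se + 2 / n_perm)
  expect_warning(permutation_group_test(sc8, g8, n_perm = 50, seed = 1),
                 "unstable")
})

test_that("Spearman distances match a brute-force rank-correlation oracle", {
  X <- toy_matrix(12, 8, seed = 47)
  cls <- toy_classes(5, 7)
  res <- hierarchical_cluster_eval(X, cls)
  d <- as.matrix(res$distance)
  for (i in 1:11) for (j in (i + 1):12) {
    oracle <- 1 - cor(rank(X[i, ]), rank(X[j, ]))
    expect_equal(d[i, j], oracle, tolerance = 1e-12)
  }
})

test_that("clustering separates well-separated classes and errors on flat profiles", {
  set.seed(48)
  cls <- toy_classes(8, 10)
  X <- matrix(rnorm(18 * 10), 18, 10,
              dimnames = list(paste0("S", 1:18), paste0("V", 1:10)))
  # give each class its own strong rank profile so Spearman distances are
  # small within classes and large between them
  prof_g <- rep(c(6, -6), length.out = 10)
  X[cls == "greater", ] <- sweep(X[cls == "greater", ], 2, prof_g, "+")
  X[cls == "lesser", ] <- sweep(X[cls == "lesser", ], 2, -prof_g, "+")
  res <- hierarchical_cluster_eval(X, cls)
  expect_equal(res$misclassified, 0)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_s3_class(res$hclust, "hclust")

  Xc <- X; Xc[3, ] <- 2
  expect_error(hierarchical_cluster_eval(Xc, cls), "S3")

  path <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(res$hclust, path)
  txt <- readLines(path)
  expect_match(txt, "^\\(.*\\);$")
})

test_that("group-score ANOVA matches hand-computed sums of squares and the t-test identity", {
  # brute-force one-way ANOVA oracle on a small three-group example
  g1 <- c(6.2, 5.9, 6.8, 7.1)
  g2 <- c(5.1, 4.8, 5.6, 5.3)
  g3 <- c(6.0, 6.4, 5.8, 6.1)
  scores <- c(g1, g2, g3)
  groups <- rep(c("a", "b", "c"), each = 4)
  grand <- mean(scores)
  ss_between <- 4 * sum((tapply(scores, groups, mean) - grand)^2)
  ss_within <- sum((scores - ave(scores, groups))^2)
  f_oracle <- (ss_between / 2) / (ss_within / 9)
  res <- group_score_anova(scores, groups, posthoc = "tukey")
  expect_equal(res$f, f_oracle, tolerance = 1e-10)
  expect_equal(res$p_anova, pf(f_oracle, 2, 9, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(nrow(res$posthoc), 3)

  # two groups: F = t^2 and identical p
  t2 <- two_sample_ttest(g1, g2)
  res2 <- group_score_anova(c(g1, g2), rep(c("a", "b"), each = 4),
                            posthoc = "bonferroni")
  expect_equal(res2$f, t2$t^2, tolerance = 1e-10)
  expect_equal(res2$p_anova, t2$p, tolerance = 1e-10)
  # a single pairwise comparison: bonferroni leaves p unchanged
  expect_equal(res2$posthoc$p_adj, t2$p, tolerance = 1e-10)

  # all groups from one distribution: large p everywhere
  set.seed(49)
  same <- rnorm(30)
  res3 <- group_score_anova(same, rep(c("a", "b", "c"), 10),
                            posthoc = "holm_sidak")
  expect_gt(res3$p_anova, 0.001)
  expect_error(group_score_anova(scores, groups, posthoc = "xxx"))

  # dunnett returns one comparison per non-reference group
  res4 <- group_score_anova(scores, groups, posthoc = "dunnett")
  expect_equal(nrow(res4$posthoc), 2)
})

test_that("Holm-Sidak step-down adjustment is correct on a hand example", {
  p <- c(0.04, 0.01)
  adj <- holm_sidak_adjust(p)
  expect_equal(adj[2], 1 - (1 - 0.01)^2)
  expect_equal(adj[1], max(0.04, 1 - (1 - 0.01)^2))
  # monotone and never below the raw p
  set.seed(51)
  pr <- runif(8)
  expect_true(all(holm_sidak_adjust(pr) >= pr))
  # sidak step-down is uniformly no larger than holm step-down
  expect_true(all(holm_sidak_adjust(pr) <= p.adjust(pr, method = "holm") + 1e-12))
})
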