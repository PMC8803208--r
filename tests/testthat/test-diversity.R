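# Correlation, PCA, k-means clustering, elbow diagnostics and Tukey group
# contrasts.

test_that("pairwise Pearson correlation behaves on exact and flagged cases", {
  df <- data.frame(genotype = letters[1:10], tcc = 1:10, b = 2 * (1:10) + 1,
                   L = rep(5, 10))
  cors <- correlate(df, vars = c("tcc", "b", "L"))
  expect_equal(cors$r[cors$var1 == "tcc" & cors$var2 == "b"], 1)
  expect_true(cors$undefined[cors$var2 == "L" & cors$var1 == "tcc"])
  expect_true(is.na(cors$r[cors$undefined][1]))
  # synthetic default panel: r(TCC, b*) near the calibrated 0.90
  tab <- generate_phenotype_table(seed = 1)
  cors2 <- correlate(tab)
  r_b <- cors2$r[cors2$var1 == "tcc" & cors2$var2 == "b"]
  expect_equal(r_b, 0.90, tolerance = 0.05)
  # chroma is induced by b*: its correlation cannot materially exceed b*'s
  r_c <- cors2$r[cors2$var1 == "tcc" & cors2$var2 == "chroma"]
  expect_lt(r_c - r_b, 0.03)
  expect_error(correlate(df[1:2, ], vars = c("tcc", "b")), "fewer than 3")
})

test_that("PCA reports valid variance proportions", {
  df <- data.frame(x = rnorm(50))
  df$y <- 3 * df$x
  p <- run_pca(df, vars = c("x", "y"))
  expect_equal(p$prop_var[1], 1, tolerance = 1e-12)
  tab <- generate_phenotype_table(seed = 2)
  p2 <- run_pca(tab)
  expect_equal(sum(p2$prop_var), 1, tolerance = 1e-12)
  expect_true(all(diff(p2$prop_var) <= 1e-12))
  expect_true(all(p2$prop_var >= 0 & p2$prop_var <= 1))
  # isotropic noise: every component near 1/p
  set.seed(4)
  iso <- as.data.frame(matrix(rnorm(500 * 4), 500, 4))
  p3 <- run_pca(iso, vars = names(iso))
  expect_true(all(abs(p3$prop_var - 0.25) < 0.06))
  bad <- data.frame(x = rnorm(10), y = rep(1, 10))
  expect_error(run_pca(bad, vars = c("x", "y")), "zero-variance")
})

test_that("elbow curve is monotone and knees where the clusters are", {
  tab <- generate_phenotype_table(seed = 4)
  e <- elbow_curve(tab, k_max = 8, seed = 1)
  expect_true(all(diff(e$wss) <= 1e-8))
  expect_lte(attr(e, "knee"), 5)
  expect_false(attr(e, "no_clear_elbow"))
  # a single isotropic blob has no pronounced knee
  set.seed(7)
  iso <- data.frame(genotype = sprintf("g%d", 1:150),
                    tcc = rnorm(150, 5, 1), L = rnorm(150, 75, 1),
                    a = rnorm(150, -5, 1), b = rnorm(150, 20, 1),
                    hue = rnorm(150, 100, 1), chroma = rnorm(150, 21, 1),
                    lightness = rnorm(150, 170, 1))
  expect_true(attr(elbow_curve(iso, k_max = 8, seed = 1), "no_clear_elbow"))
  expect_error(elbow_curve(tab, k_max = 0), "k_max")
  expect_error(elbow_curve(tab[1:5, ], k_max = 5), "k_max")
})

test_that("k-means clustering recovers the generated groups", {
  tab <- generate_phenotype_table(seed = 3, noise_scale = 0.1)
  cl <- cluster_genotypes(tab, k = 5, seed = 1)
  expect_gt(rand_index(cl$assignments, tab$cluster), 0.95)
  expect_equal(sort(cl$sizes), sort(c(76, 34, 26, 21, 71)))
  # canonical labels: cluster 1 has the highest mean TCC
  m <- tapply(tab$tcc, cl$assignments, mean)
  expect_equal(order(m, decreasing = TRUE), 1:5)
  # k = 1: one cluster, within-SS equals the total SS of standardized vars
  c1 <- cluster_genotypes(tab, k = 1, seed = 1)
  expect_equal(unique(c1$assignments), 1L)
  X <- scale(as.matrix(as.data.frame(tab)[, c("tcc", cp_features)]))
  expect_equal(c1$tot_withinss, sum(X^2), tolerance = 1e-8)
  # k = n on distinct points: within-SS is 0
  small <- tab[seq(1, 228, by = 24), ]
  cn <- cluster_genotypes(small, k = nrow(small), seed = 1)
  expect_equal(cn$tot_withinss, 0, tolerance = 1e-9)
  expect_error(cluster_genotypes(tab, k = 300), "between 1")
})

test_that("rand index scores partitions independently of labels", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(rand_index(a, a), 1)
  expect_equal(rand_index(a, c(3, 3, 1, 1, 2, 2)), 1)  # permuted labels
  expect_lt(rand_index(a, c(1, 2, 1, 2, 1, 2)), 1)
})

test_that("group contrasts assign compact letters correctly", {
  set.seed(10)
  # two identical groups share a letter
  df <- data.frame(tcc = rep(rnorm(20, 5, 1), 2))
  g <- rep(1:2, each = 20)
  out <- compare_groups(df, g, vars = "tcc")
  expect_equal(out$letters[1], out$letters[2])
  # one strongly shifted group gets its own letter
  base <- rnorm(20, 5, 0.3)
  df2 <- data.frame(tcc = c(base, base, rnorm(20, 15, 0.3)))
  g2 <- rep(1:3, each = 20)
  out2 <- compare_groups(df2, g2, vars = "tcc")
  expect_equal(out2$letters[1], out2$letters[2])
  expect_false(out2$letters[3] %in% out2$letters[1:2])
  # the high-TCC synthetic group is separated on TCC
  tab <- generate_phenotype_table(seed = 5)
  oc <- compare_groups(tab, tab$cluster, vars = "tcc")
  g4 <- oc[oc$group == "4", ]
  others <- oc[oc$group != "4", ]
  expect_equal(g4$mean, 10.74, tolerance = 0.9)
  expect_false(any(grepl(g4$letters, others$letters, fixed = TRUE)))
  expect_error(compare_groups(tab, rep(1, nrow(tab))), ">= 2 groups")
  expect_error(compare_groups(tab[1:5, ], c(1, 1, 1, 1, 2)), ">= 2 members")
})
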