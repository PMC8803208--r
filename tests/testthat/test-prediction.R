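# Metrics against brute-force oracles, learner contracts, importance and
# feature reduction, fold plans, and the benchmark harness.

test_that("metrics match hand-computed and brute-force values", {
  expect_equal(metric_r2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(metric_r2(c(1, 2, 3), rep(2, 3)), 0)
  # hand arithmetic: sum((pred - 2)^2) / sum((obs - 2)^2)
  expect_equal(metric_r2(c(1, 2, 3), c(1.1, 1.9, 3.0)),
               (0.9^2 + 0.1^2 + 1^2) / 2)
  expect_equal(metric_rmse(c(5, 5), c(5, 5)), 0)
  expect_equal(metric_rmse(c(0, 2), c(2, 2)), sqrt(2))
  expect_equal(metric_mape(c(2, 4), c(1, 5)), 0.375)
  expect_equal(metric_mape(c(10, 20), c(11, 22)), 0.10)
  # homogeneity: scaling both vectors scales RMSE
  set.seed(3)
  o <- rnorm(20); p <- rnorm(20)
  expect_equal(metric_rmse(3 * o, 3 * p), 3 * metric_rmse(o, p))
  expect_warning(metric_mape(c(0, 2), c(1, 2)), "zero observation")
  expect_error(metric_r2(rep(1, 5), rnorm(5)), "constant")
  expect_error(metric_rmse(numeric(0), numeric(0)), "non-empty")
})

test_that("metrics agree with independent brute-force recomputation to 1e-12", {
  set.seed(11)
  for (i in 1:10) {
    obs <- rnorm(37, 5, 2); pred <- obs + rnorm(37, 0, 0.5)
    r2_bf <- { s1 <- 0; s2 <- 0; m <- sum(obs) / length(obs)
      for (k in seq_along(obs)) { s1 <- s1 + (pred[k] - m)^2
                                  s2 <- s2 + (obs[k] - m)^2 }
      s1 / s2 }
    rmse_bf <- { s <- 0
      for (k in seq_along(obs)) s <- s + (pred[k] - obs[k])^2
      sqrt(s / length(obs)) }
    mape_bf <- { s <- 0
      for (k in seq_along(obs)) s <- s + abs(obs[k] - pred[k]) / abs(obs[k])
      s / length(obs) }
    expect_lt(abs(metric_r2(obs, pred) - r2_bf), 1e-12)
    expect_lt(abs(metric_rmse(obs, pred) - rmse_bf), 1e-12)
    expect_lt(abs(metric_mape(obs, pred) - mape_bf), 1e-12)
    expect_lt(abs(metric_r2_cor(obs, pred) - cor(obs, pred)^2), 1e-12)
  }
})

test_that("selection-based linear learners recover an exact linear law", {
  set.seed(21)
  n <- 60
  train <- data.frame(b = runif(n, 5, 60), L = runif(n, 60, 90))
  train$tcc <- 2 * train$b + 1
  test <- data.frame(b = runif(20, 5, 60), L = runif(20, 60, 90))
  test$tcc <- 2 * test$b + 1
  for (id in c("LRFS", "LRBS", "LRSS", "GLMSS")) {
    p <- fit_predict(id, train, c("b", "L"), test)
    expect_lt(metric_rmse(test$tcc, p), 1e-8)
  }
  # PLS at full rank is OLS on this exactly-linear problem
  p <- fit_predict(model_spec("PLS", list(ncomp = 2)), train, c("b", "L"), test)
  expect_lt(metric_rmse(test$tcc, p), 1e-6)
})

test_that("every learner fits and predicts finite values in range", {
  tab <- generate_phenotype_table(seed = 2)
  set.seed(9)
  tr <- sample(nrow(tab), 180)
  train <- tab[tr, ]; test <- tab[-tr, ]
  for (m in bench_models(ntree = 50)) {
    set.seed(7)
    p <- fit_predict(m, train, cp_features, test)
    expect_true(all(is.finite(p)), info = m$id)
    expect_gt(metric_r2_cor(test$tcc, p), 0.6)  # honest signal, every learner
  }
})

test_that("constant targets are handled without crashing", {
  train <- data.frame(b = 1:20, L = rnorm(20), tcc = rep(5, 20))
  test <- train[1:5, ]
  p <- fit_predict("CART", train, c("b", "L"), test)
  expect_equal(metric_rmse(test$tcc, p), 0)
  expect_error(metric_r2(test$tcc, p), "constant")
})

test_that("fit_predict validates its inputs", {
  tab <- generate_phenotype_table(seed = 2)
  expect_error(fit_predict("LRFS", tab, c("nope"), tab), "missing columns")
  expect_error(fit_predict("LRFS", tab[1:3, ], cp_features, tab), "training rows")
  expect_error(model_spec("XXX"))
  expect_error(model_spec("RF", list(bogus = 1)), "unknown hyperparameter")
})

test_that("relative importance finds the driver and rescales to 100", {
  # single feature: trivially 100
  tab <- generate_phenotype_table(seed = 4)
  set.seed(2)
  imp1 <- relative_importance("RR", tab, "b")
  expect_equal(unname(imp1["b"]), 100)
  # only b drives tcc; pure-noise features must stay below 50 for RF
  set.seed(5)
  n <- 200
  drv <- data.frame(b = runif(n, 5, 60), n1 = rnorm(n), n2 = rnorm(n))
  drv$tcc <- 0.2 * drv$b + rnorm(n, 0, 0.3)
  set.seed(6)
  imp_rf <- relative_importance(model_spec("RF", list(ntree = 100)), drv,
                                c("b", "n1", "n2"))
  expect_equal(unname(imp_rf["b"]), 100)
  expect_true(all(imp_rf[c("n1", "n2")] < 50))
  # brute-force permutation oracle agrees on the ranking
  set.seed(6)
  imp_perm <- relative_importance(model_spec("RF", list(ntree = 100)), drv,
                                  c("b", "n1", "n2"), method = "permutation")
  expect_equal(names(which.max(imp_perm)), "b")
  # collinear duplicate: neither copy is forced to zero by rescaling
  dup <- drv
  dup$b2 <- dup$b + rnorm(n, 0, 0.5)
  set.seed(7)
  imp_dup <- relative_importance(model_spec("RF", list(ntree = 100)), dup,
                                 c("b", "b2", "n1"))
  expect_true(all(imp_dup[c("b", "b2")] > 50))
})

test_that("feature reduction applies the 50% threshold faithfully", {
  prof <- c(b = 100, chroma = 100, hue = 60, lightness = 55, a = 52, L = 30)
  expect_equal(reduce_features(prof), c("b", "chroma", "hue", "lightness", "a"),
               ignore_attr = TRUE)
  expect_equal(reduce_features(c(x = 100, y = 100)), c("x", "y"),
               ignore_attr = TRUE)
  rf_prof <- c(b = 100, hue = 70, chroma = 100, a = 40, L = 20, lightness = 45)
  expect_equal(reduce_features(rf_prof), c("b", "hue", "chroma"),
               ignore_attr = TRUE)
  expect_warning(kept <- reduce_features(c(u = 10, v = 40)), "top-1")
  expect_equal(kept, "v", ignore_attr = TRUE)
  expect_true(attr(kept, "fallback_top1"))
  expect_error(reduce_features(numeric(0)), "empty")
})

test_that("fold plans respect fractions, disjointness and determinism", {
  tab10 <- blob_table(n = 10, seed = 1)
  plans <- make_folds(tab10, cv_scheme("V-Random", outer_repeats = 10, seed = 2))
  for (p in plans) {
    expect_equal(length(p$train), 8)
    expect_equal(length(p$validation), 2)
    expect_length(intersect(p$train, p$validation), 0)
  }
  tab <- generate_phenotype_table(seed = 1)
  p3 <- make_folds(tab, cv_scheme("IV-Random", outer_repeats = 3, seed = 2))
  sizes <- vapply(p3, function(p)
    c(length(p$train), length(p$validation), length(p$test)), numeric(3))
  expect_true(all(colSums(sizes) == 228))
  expect_true(all(abs(sizes[1, ] - 0.6 * 228) <= 1))
  for (p in p3)
    expect_length(Reduce(intersect, list(p$train, p$validation, p$test)), 0)
  # IV-Cluster: one plan per cluster, test = the whole held-out cluster
  pc <- make_folds(tab, cv_scheme("IV-Cluster", seed = 2))
  expect_length(pc, 5)
  for (p in pc) {
    expect_setequal(p$test, which(tab$cluster == p$cluster))
    expect_false(any(tab$cluster[c(p$train, p$validation)] == p$cluster))
  }
  # determinism
  expect_identical(make_folds(tab, cv_scheme("V-Random", seed = 5)),
                   make_folds(tab, cv_scheme("V-Random", seed = 5)))
  expect_error(make_folds(tab[, -9], cv_scheme("IV-Cluster")), "cluster")
  expect_error(cv_scheme("V-Random", fractions = c(train = 0.5,
                                                   validation = 0.2)),
               "sum to 1")
})

test_that("ANN approaches the generator's linear noise ceiling", {
  # oracle ceiling: OLS trained and evaluated on very large independent
  # panels approximates the best attainable R2 given the color-model noise
  grow <- function(f, seed) generate_phenotype_table(
    lapply(default_cluster_specs(),
           function(s) { s$n_genotypes <- s$n_genotypes * f; s }), seed = seed)
  big <- grow(15L, 101); bigtest <- grow(15L, 202)
  fml <- stats::as.formula(paste("tcc ~", paste(cp_features, collapse = "+")))
  ceiling_r2 <- metric_r2_cor(bigtest$tcc,
                              predict(stats::lm(fml, data = big), bigtest))
  tab <- generate_phenotype_table(seed = 1)
  b <- run_benchmark(tab, models = "ANN",
                     schemes = list(cv_scheme("V-Random", outer_repeats = 3,
                                              seed = 5)), seed = 5)
  ann_r2 <- b$summary$r2_cor[b$summary$variant == "complete"]
  expect_equal(ann_r2, ceiling_r2, tolerance = 0.05)
})

test_that("benchmark grid is complete, deterministic and leak-free by design", {
  tab <- generate_phenotype_table(seed = 2)
  schemes <- list(cv_scheme("V-Random", outer_repeats = 2, seed = 3),
                  cv_scheme("IV-Cluster", seed = 4))
  run <- function() run_benchmark(tab, models = c("LRSS", "CART"),
                                  schemes = schemes, seed = 6,
                                  store_predictions = TRUE)
  b1 <- run(); b2 <- run()
  expect_identical(b1$results, b2$results)
  expect_setequal(unique(b1$results$model), c("LRSS", "CART"))
  expect_setequal(unique(b1$results$scheme), c("V-Random", "IV-Cluster"))
  expect_setequal(unique(b1$results$variant), c("complete", "reduced"))
  # every IV-Cluster evaluation row on 'test' scores exactly one held-out
  # cluster, never seen in training
  ivc <- b1$predictions[b1$predictions$scheme == "IV-Cluster" &
                        b1$predictions$partition == "test", ]
  for (f in unique(ivc$fold)) {
    geno <- unique(ivc$genotype[ivc$fold == f])
    expect_equal(length(unique(tab$cluster[tab$genotype %in% geno])), 1L)
  }
  # stored predictions reproduce the reported metrics exactly
  one <- b1$results[b1$results$model == "CART" &
                    b1$results$scheme == "V-Random" &
                    b1$results$variant == "complete" & b1$results$plan == 1, ]
  pr <- b1$predictions[b1$predictions$model == "CART" &
                       b1$predictions$scheme == "V-Random" &
                       b1$predictions$variant == "complete" &
                       b1$predictions$fold == 1, ]
  expect_lt(abs(metric_rmse(pr$observed, pr$predicted) - one$rmse), 1e-12)
  expect_lt(abs(metric_r2(pr$observed, pr$predicted) - one$r2), 1e-12)
})

test_that("paired complete-vs-reduced comparison flags the degenerate cases", {
  mk <- function(r2c, r2r) {
    n <- length(r2c)
    data.frame(model = "M", scheme = "V-Random",
               variant = rep(c("complete", "reduced"), each = n),
               plan = rep(seq_len(n), 2), partition = "validation",
               cluster = NA, r2 = c(r2c, r2r), r2_cor = c(r2c, r2r),
               rmse = 0.3, mape = 0.05, n = 40)
  }
  same <- compare_variants(mk(rep(0.9, 5), rep(0.9, 5)))
  expect_equal(same$p, 1)
  expect_true(same$ns)
  off <- compare_variants(mk(rep(0.9, 5), rep(0.8, 5)))
  expect_equal(off$p, 0)
  expect_true(off$degenerate)
  # rejection rate of a true shift matches the closed-form power of the
  # paired t-test within a binomial 99% band
  set.seed(12)
  n_pairs <- 30; shift <- 0.05; sdd <- 0.1; sims <- 200
  rejections <- mean(replicate(sims, {
    d <- rnorm(n_pairs, shift, sdd)
    res <- compare_variants(mk(0.9 + d, rep(0.9, n_pairs)))
    !res$ns
  }))
  want <- stats::power.t.test(n = n_pairs, delta = shift, sd = sdd,
                              type = "paired")$power
  ci <- want + c(-1, 1) * 2.58 * sqrt(want * (1 - want) / sims)
  expect_gte(rejections, ci[1] - 1e-9)
  expect_lte(rejections, ci[2] + 1e-9)
})
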