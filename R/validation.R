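# Cross-validation schemes, evaluation metrics, relative importance and the
# complete-vs-reduced benchmark harness.

#' Coefficient of determination (explained-variation ratio)
#'
#' `sum((yhat_i - ybar)^2) / sum((y_i - ybar)^2)` with `ybar` the observed
#' mean. This is the ratio as conventionally printed by phenotyping studies;
#' note it can exceed 1 for biased predictions, so [metric_r2_cor()] (squared
#' Pearson correlation, bounded by 1) is reported alongside it everywhere.
#'
#' @param obs,pred numeric vectors of equal length; `obs` must not be
#'   constant.
#' @return R-squared.
#' @export
metric_r2 <- function(obs, pred) {
  .cp_check_metric_input(obs, pred)
  if (stats::sd(obs) == 0) stop("R2 undefined: constant observations")
  sum((pred - mean(obs))^2) / sum((obs - mean(obs))^2)
}

#' Squared Pearson correlation between observations and predictions
#' @inheritParams metric_r2
#' @return Squared correlation in \[0, 1\]; 0 when predictions are constant.
#' @export
metric_r2_cor <- function(obs, pred) {
  .cp_check_metric_input(obs, pred)
  if (stats::sd(obs) == 0) stop("R2 undefined: constant observations")
  if (stats::sd(pred) == 0) return(0)
  stats::cor(obs, pred)^2
}

#' Root-mean-square error
#' @inheritParams metric_r2
#' @return RMSE, same units as `obs`.
#' @export
metric_rmse <- function(obs, pred) {
  .cp_check_metric_input(obs, pred)
  sqrt(mean((pred - obs)^2))
}

#' Mean absolute percentage error (as a fraction)
#'
#' `(1/n) sum(|y_t - yhat_t| / |y_t|)`, reported as a fraction (0.05 = 5%).
#' Zero observations are excluded with a warning.
#'
#' @inheritParams metric_r2
#' @return MAPE as a fraction.
#' @export
metric_mape <- function(obs, pred) {
  .cp_check_metric_input(obs, pred)
  zero <- obs == 0
  if (any(zero)) {
    warning(sum(zero), " zero observation(s) excluded from MAPE")
    obs <- obs[!zero]; pred <- pred[!zero]
    if (!length(obs)) stop("no nonzero observations for MAPE")
  }
  mean(abs(obs - pred) / abs(obs))
}

.cp_check_metric_input <- function(obs, pred) {
  if (!length(obs) || length(obs) != length(pred))
    stop("obs and pred must be non-empty vectors of equal length")
  if (anyNA(obs) || anyNA(pred)) stop("NA in metric input")
  invisible(NULL)
}

#' Cross-validation scheme
#'
#' Three designs: `"V-Random"` — repeated random 80/20 train/validation
#' splits; `"IV-Random"` — repeated random 60/20/20 train/validation/test
#' splits; `"IV-Cluster"` — leave-one-cluster-out: each cluster in turn is
#' the test set, the remaining clusters are split into train/validation.
#' Splits are stratified on TCC quintiles. `folds` x `repetitions`
#' inner-resampling assignments of the training rows are generated with each
#' plan for learners that tune.
#'
#' @param name scheme name.
#' @param fractions split fractions (must sum to 1); defaults per scheme.
#' @param folds,repetitions inner resampling design (default 6-fold x 5).
#' @param outer_repeats number of outer random repeats (default 30; ignored
#'   by IV-Cluster, which has one plan per cluster).
#' @param seed integer seed.
#' @return Object of class `cp_scheme`.
#' @export
cv_scheme <- function(name = c("V-Random", "IV-Random", "IV-Cluster"),
                      fractions = NULL, folds = 6L, repetitions = 5L,
                      outer_repeats = 30L, seed = 1L) {
  name <- match.arg(name)
  if (is.null(fractions)) {
    fractions <- switch(name,
      "V-Random"   = c(train = 0.8, validation = 0.2),
      "IV-Random"  = c(train = 0.6, validation = 0.2, test = 0.2),
      "IV-Cluster" = c(train = 0.8, validation = 0.2))
  }
  if (abs(sum(fractions) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (folds < 2) stop("folds must be >= 2")
  structure(list(name = name, fractions = fractions, folds = as.integer(folds),
                 repetitions = as.integer(repetitions),
                 outer_repeats = as.integer(outer_repeats),
                 seed = as.integer(seed)),
            class = "cp_scheme")
}

# Stratified assignment of n rows to named fractions using TCC quintile bins.
# Global partition sizes are exact (largest-remainder rounding); rows are
# spread over the bins as evenly as the counts allow.
.cp_strat_split <- function(y, fractions) {
  n <- length(y)
  parts <- names(fractions)
  target <- floor(n * fractions)
  rem <- n - sum(target)
  if (rem > 0) {
    ord <- order(n * fractions - target, decreasing = TRUE)[seq_len(rem)]
    target[ord] <- target[ord] + 1
  }
  if (any(target == 0)) {  # every partition must be non-empty
    donor <- which.max(target)
    target[target == 0] <- 1
    target[donor] <- target[donor] - (sum(target) - n)
  }
  bins <- cut(rank(y, ties.method = "first"), breaks = min(5, n),
              labels = FALSE)
  out <- character(n)
  assigned <- stats::setNames(rep(0, length(parts)), parts)
  pool <- integer(0)
  for (b in unique(bins)) {
    idx <- which(bins == b)
    idx <- idx[sample.int(length(idx))]
    m <- length(idx)
    counts <- pmin(floor(fractions * m), pmax(target - assigned, 0))
    take <- sum(counts)
    if (take > 0) out[idx[seq_len(take)]] <- sample(rep(parts, times = counts))
    if (take < m) pool <- c(pool, idx[seq.int(take + 1, m)])
    assigned <- assigned + counts
  }
  pool <- pool[sample.int(length(pool))]
  for (p in parts) {
    need <- target[p] - assigned[p]
    if (need > 0) {
      out[pool[seq_len(need)]] <- p
      pool <- pool[-seq_len(need)]
    }
  }
  out
}

#' Build the partition plans for a scheme
#'
#' @param table phenotype table (IV-Cluster requires a `cluster` column with
#'   at least two clusters of >= 2 members).
#' @param scheme a [cv_scheme()].
#' @return List of plans; each plan is a list with integer row indices
#'   `train`, `validation`, optionally `test`, the plan `id`, the held-out
#'   `cluster` (IV-Cluster only) and `inner`, a folds x repetitions inner
#'   fold-assignment matrix over the training rows. Deterministic given the
#'   scheme's seed.
#' @export
make_folds <- function(table, scheme) {
  stopifnot(inherits(scheme, "cp_scheme"))
  n <- nrow(table)
  y <- table$tcc
  set.seed(scheme$seed)
  inner_of <- function(train_idx) {
    m <- length(train_idx)
    sapply(seq_len(scheme$repetitions),
           function(r) sample(rep_len(seq_len(scheme$folds), m)))
  }
  plans <- list()
  if (scheme$name == "IV-Cluster") {
    if (!"cluster" %in% names(table))
      stop("IV-Cluster requires a 'cluster' column")
    cl <- table$cluster
    ids <- sort(unique(cl))
    if (length(ids) < 2) stop("IV-Cluster requires >= 2 clusters")
    if (any(table(cl) < 2)) stop("every cluster needs >= 2 members")
    for (c_out in ids) {
      test <- which(cl == c_out)
      rest <- which(cl != c_out)
      lab <- .cp_strat_split(y[rest], scheme$fractions)
      train <- rest[lab == "train"]; val <- rest[lab == "validation"]
      plans[[length(plans) + 1L]] <- list(
        id = length(plans) + 1L, train = train, validation = val,
        test = test, cluster = c_out, inner = inner_of(train))
    }
  } else {
    for (r in seq_len(scheme$outer_repeats)) {
      lab <- .cp_strat_split(y, scheme$fractions)
      plan <- list(id = r, train = which(lab == "train"),
                   validation = which(lab == "validation"),
                   cluster = NA)
      if ("test" %in% names(scheme$fractions)) plan$test <- which(lab == "test")
      plan$inner <- inner_of(plan$train)
      plans[[r]] <- plan
    }
  }
  plans
}

#' Relative importance of features for one model (0-100 scale)
#'
#' Model-appropriate raw importances — absolute t-values of retained terms
#' for the stepwise linear family, |standardized coefficients| for ridge and
#' the Bayesian shrinkage models, VIP loading-weight scores for PLS, summed
#' split variance reduction for CART and RF — rescaled so the top feature is
#' 100. ANN and SVM have no native importance; for them (or with
#' `method = "permutation"`) a permutation importance is computed strictly
#' inside the training data: the model is refitted on 80% of the rows and
#' each feature is permuted in the remaining 20%, recording the RMSE
#' increase, averaged over `n_perm` shuffles.
#'
#' @param spec a [model_spec()] or id string.
#' @param train training table (with `tcc`).
#' @param features feature names.
#' @param method `"native"` (default; falls back to permutation where no
#'   native importance exists) or `"permutation"`.
#' @param n_perm permutation repeats (default 3).
#' @param fit optional: an existing [cp_fit()] on the full training data,
#'   reused for native importances.
#' @return Named numeric vector on 0-100 with attribute `all_zero`.
#' @export
relative_importance <- function(spec, train, features,
                                method = c("native", "permutation"),
                                n_perm = 3, fit = NULL) {
  if (is.character(spec)) spec <- model_spec(spec)
  method <- match.arg(method)
  X <- as.matrix(as.data.frame(train)[, features, drop = FALSE])
  y <- train$tcc
  native_fun <- switch(spec$id,
    LRFS = , LRBS = , LRSS = , GLMSS = function(f) .cp_importance_steplm(f, features),
    RR   = function(f) .cp_importance_ridge(f, features),
    PLS  = function(f) .cp_importance_pls(f, features),
    BL   = , BBL = function(f) .cp_importance_linear_beta(f, features),
    RF   = , CART = function(f) stats::setNames(
      if (spec$id == "RF") f$importance else .cp_tree_importance(f$nodes, length(features)),
      features),
    NULL)
  if (method == "native" && !is.null(native_fun)) {
    if (is.null(fit)) fit <- cp_fit(spec, X, y)
    raw <- native_fun(fit)
  } else {
    raw <- .cp_permutation_importance(spec, X, y, n_perm)
  }
  raw <- pmax(raw, 0)
  all_zero <- max(raw) <= 0
  out <- if (all_zero) raw else raw / max(raw) * 100
  attr(out, "all_zero") <- all_zero
  if (all_zero) warning("all importances are zero for ", spec$id)
  out
}

# permutation importance on an internal 80/20 split of the training data
.cp_permutation_importance <- function(spec, X, y, n_perm) {
  n <- nrow(X)
  hold <- sample.int(n, max(2L, round(0.2 * n)))
  fit <- cp_fit(spec, X[-hold, , drop = FALSE], y[-hold])
  Xh <- X[hold, , drop = FALSE]
  base <- metric_rmse(y[hold], predict(fit, Xh))
  raw <- stats::setNames(numeric(ncol(X)), colnames(X))
  for (j in seq_len(ncol(X))) {
    inc <- 0
    for (r in seq_len(n_perm)) {
      Xp <- Xh
      Xp[, j] <- Xp[sample.int(nrow(Xp)), j]
      inc <- inc + metric_rmse(y[hold], predict(fit, Xp)) - base
    }
    raw[j] <- inc / n_perm
  }
  raw
}

#' Reduce a feature set by relative importance
#'
#' Keeps features whose relative importance is at or above `threshold`
#' percent, preserving the profile's order. Never returns an empty set: if
#' everything falls below the threshold the single most important feature is
#' kept and flagged.
#'
#' @param profile named importance vector (0-100), e.g. from
#'   [relative_importance()].
#' @param threshold percent cutoff (default 50).
#' @return Character vector of retained features; attribute `fallback_top1`
#'   is `TRUE` when the top-1 fallback was used.
#' @export
reduce_features <- function(profile, threshold = 50) {
  if (!length(profile)) stop("empty importance profile")
  keep <- names(profile)[profile >= threshold]
  fallback <- FALSE
  if (!length(keep)) {
    keep <- names(profile)[which.max(profile)]
    fallback <- TRUE
    warning("no feature reached the threshold; keeping top-1 (", keep, ")")
  }
  attr(keep, "fallback_top1") <- fallback
  keep
}

#' Run the complete-vs-reduced benchmark over models and schemes
#'
#' For every scheme x model x partition plan: fit the complete model on the
#' training rows, score feature importance on the training data only, derive
#' the reduced (>= threshold) feature set, refit, and evaluate both variants
#' on the plan's held-out rows. Per-cell failures are recorded, they do not
#' abort the grid.
#'
#' @param table phenotype table (needs `tcc`, the six indices, and `cluster`
#'   when an IV-Cluster scheme is included).
#' @param models character ids or [model_spec()] list (default: all twelve).
#' @param schemes list of [cv_scheme()] (default: the three designs with 30
#'   outer repeats).
#' @param features feature columns (default the six colorimetric indices).
#' @param threshold reduced-model importance cutoff (default 50).
#' @param seed integer; master seed for all fitting randomness.
#' @param store_predictions keep per-plan observed/predicted pairs.
#' @return Object of class `cp_benchmark`: list with `results` (one row per
#'   model x scheme x plan x variant x partition), `summary` (means of the
#'   evaluation partition: validation for V-Random, test otherwise),
#'   `importance` (mean 0-100 profile per model x scheme), `reduced`
#'   (modal reduced feature set per model x scheme), `ttests`
#'   (complete vs reduced paired t-tests) and optionally `predictions`.
#' @export
run_benchmark <- function(table,
                          models = cp_models(),
                          schemes = list(cv_scheme("V-Random"),
                                         cv_scheme("IV-Random"),
                                         cv_scheme("IV-Cluster")),
                          features = c("L", "a", "b", "hue", "chroma",
                                       "lightness"),
                          threshold = 50, seed = 1L,
                          store_predictions = FALSE) {
  specs <- lapply(models, function(m) if (is.character(m)) model_spec(m) else m)
  miss <- setdiff(c(features, "tcc"), names(table))
  if (length(miss)) stop("table is missing columns: ", paste(miss, collapse = ", "))
  results <- list()
  predictions <- list()
  imp_acc <- list()
  red_acc <- list()
  X_all <- as.data.frame(table)
  for (scheme in schemes) {
    plans <- make_folds(table, scheme)
    for (mi in seq_along(specs)) {
      spec <- specs[[mi]]
      for (plan in plans) {
        set.seed((seed * 100 + plan$id * 1000 + mi * 7) %% .Machine$integer.max)
        cell <- tryCatch(
          .cp_bench_cell(spec, X_all, plan, features, threshold, scheme$name),
          error = function(e) {
            warning("cell failed (", spec$id, ", ", scheme$name, ", plan ",
                    plan$id, "): ", conditionMessage(e))
            NULL
          })
        if (is.null(cell)) next
        results[[length(results) + 1L]] <- cell$rows
        key <- paste(spec$id, scheme$name, sep = "|")
        imp_acc[[key]] <- c(imp_acc[[key]], list(cell$importance))
        red_acc[[key]] <- c(red_acc[[key]], list(cell$reduced))
        if (store_predictions)
          predictions[[length(predictions) + 1L]] <- cell$predictions
      }
    }
  }
  results <- do.call(rbind, results)
  importance <- lapply(imp_acc, function(lst) Reduce(`+`, lst) / length(lst))
  reduced <- lapply(red_acc, function(lst) {
    sets <- vapply(lst, function(s) paste(sort(s), collapse = ","), character(1))
    strsplit(names(sort(table(sets), decreasing = TRUE))[1], ",")[[1]]
  })
  out <- list(results = results,
              summary = .cp_bench_summary(results),
              importance = importance, reduced = reduced,
              ttests = compare_variants(results),
              threshold = threshold, seed = seed)
  if (store_predictions) out$predictions <- do.call(rbind, predictions)
  class(out) <- "cp_benchmark"
  out
}

# one benchmark cell: fit complete + reduced, evaluate all held-out partitions
.cp_bench_cell <- function(spec, df, plan, features, threshold, scheme_name) {
  train <- df[plan$train, , drop = FALSE]
  imp <- relative_importance(spec, train, features)
  red_feats <- reduce_features(imp, threshold)
  parts <- list(validation = plan$validation)
  if (!is.null(plan$test)) parts$test <- plan$test
  rows <- list(); preds <- list()
  for (variant in c("complete", "reduced")) {
    feats <- if (variant == "complete") features else red_feats
    fit <- cp_fit(spec, as.matrix(train[, feats, drop = FALSE]), train$tcc)
    for (pname in names(parts)) {
      idx <- parts[[pname]]
      obs <- df$tcc[idx]
      pred <- predict(fit, as.matrix(df[idx, feats, drop = FALSE]))
      rows[[length(rows) + 1L]] <- data.frame(
        model = spec$id, scheme = scheme_name, variant = variant,
        plan = plan$id, partition = pname,
        cluster = if (is.null(plan$cluster)) NA else plan$cluster,
        r2 = metric_r2(obs, pred), r2_cor = metric_r2_cor(obs, pred),
        rmse = metric_rmse(obs, pred), mape = metric_mape(obs, pred),
        n = length(obs))
      preds[[length(preds) + 1L]] <- data.frame(
        genotype = df$genotype[idx], model = spec$id, scheme = scheme_name,
        variant = variant, fold = plan$id, partition = pname,
        observed = obs, predicted = pred)
    }
  }
  list(rows = do.call(rbind, rows), importance = imp, reduced = red_feats,
       predictions = do.call(rbind, preds))
}

# evaluation partition per scheme: V-Random has no test set
.cp_eval_partition <- function(scheme) {
  ifelse(scheme == "V-Random", "validation", "test")
}

.cp_bench_summary <- function(results) {
  keep <- results[results$partition == .cp_eval_partition(results$scheme), ]
  agg <- stats::aggregate(keep[, c("r2", "r2_cor", "rmse", "mape")],
                          by = list(model = keep$model, scheme = keep$scheme,
                                    variant = keep$variant),
                          FUN = mean)
  agg[order(agg$scheme, agg$model, agg$variant), ]
}

#' Paired complete-vs-reduced comparison
#'
#' Two-sided paired t-test on the per-plan R-squared of the complete vs the
#' reduced variant for every model x scheme, on the scheme's evaluation
#' partition. Identical pairs give p = 1 ("ns"); a constant nonzero
#' difference is reported as significant and flagged degenerate.
#'
#' @param results the `results` data.frame of a [run_benchmark()].
#' @return data.frame with `model, scheme, n_pairs, mean_diff, p, ns,
#'   degenerate`.
#' @export
compare_variants <- function(results) {
  keep <- results[results$partition == .cp_eval_partition(results$scheme), ]
  out <- list()
  for (sc in unique(keep$scheme)) for (m in unique(keep$model)) {
    sub <- keep[keep$scheme == sc & keep$model == m, ]
    comp <- sub[sub$variant == "complete", c("plan", "r2")]
    red <- sub[sub$variant == "reduced", c("plan", "r2")]
    mrg <- merge(comp, red, by = "plan", suffixes = c("_c", "_r"))
    if (nrow(mrg) < 3) next
    d <- mrg$r2_c - mrg$r2_r
    degenerate <- stats::sd(d) < 1e-12
    p <- if (degenerate) {
      if (abs(mean(d)) < 1e-12) 1 else 0
    } else {
      stats::t.test(d)$p.value
    }
    out[[length(out) + 1L]] <- data.frame(
      model = m, scheme = sc, n_pairs = nrow(mrg), mean_diff = mean(d),
      p = p, ns = p >= 0.05, degenerate = degenerate)
  }
  do.call(rbind, out)
}

#' @export
print.cp_benchmark <- function(x, ...) {
  cat("<benchmark>", length(unique(x$results$model)), "models x",
      length(unique(x$results$scheme)), "schemes;",
      nrow(x$results), "evaluation rows\n")
  print(x$summary, digits = 3)
  invisible(x)
}
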